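#' Global temperature extrema of a cohort
#'
#' DIT features based on gray-scale images require every frame of every exam
#' to be quantized under one shared affine map, so gray levels are comparable
#' across frames and breasts. This scans every cell of every frame (the full
#' frame by default, not just the ROI) and returns the global extrema.
#'
#' @param cohort A `thermal_cohort`.
#' @param roi_only If `TRUE`, restrict the scan to in-ROI cells.
#' @return A `global_scale` object with fields `min` and `max` (degC).
#' @export
global_extrema <- function(cohort, roi_only = FALSE) {
  if (length(cohort$sequences) == 0L) abort("empty cohort")
  lo <- Inf
  hi <- -Inf
  for (s in cohort$sequences) {
    for (i in seq_along(s$frames)) {
      v <- if (roi_only) s$frames[[i]][s$masks[[i]]] else s$frames[[i]]
      lo <- min(lo, min(v))
      hi <- max(hi, max(v))
    }
  }
  global_scale(lo, hi)
}

#' Construct a gray-scale quantization range
#'
#' @param min,max Lowest and highest temperature (degC) over the study.
#' @return A `global_scale` object.
#' @export
global_scale <- function(min, max) {
  if (!is.finite(min) || !is.finite(max)) abort("scale extrema must be finite")
  if (max <= min) {
    abort(sprintf("degenerate gray scale: max (%g) must exceed min (%g)", max, min))
  }
  structure(list(min = min, max = max), class = "global_scale")
}

#' @export
print.global_scale <- function(x, ...) {
  cat(sprintf("<global_scale> [%g, %g] degC -> [0, 255]\n", x$min, x$max))
  invisible(x)
}

#' Quantize a temperature array to an 8-bit gray image
#'
#' Each temperature maps affinely to `255 * (T - min) / (max - min)`,
#' rounded to the nearest integer (half away from zero) and clipped to
#' `[0, 255]`; values outside the training extrema (possible for new exams)
#' clip rather than error. The map is monotone, so ordering of temperatures
#' is preserved in gray levels.
#'
#' @param values Numeric temperature matrix (degC).
#' @param scale A `global_scale`.
#' @return Integer matrix with values in `[0, 255]`.
#' @export
to_gray <- function(values, scale) {
  stopifnot_matrix(values, "values")
  if (!inherits(scale, "global_scale")) abort("`scale` must be a global_scale")
  g <- 255 * (values - scale$min) / (scale$max - scale$min)
  # round half away from zero (all values are >= 0 after clipping anyway)
  g <- pmin(pmax(g, 0), 255)
  gi <- floor(g + 0.5)
  storage.mode(gi) <- "integer"
  matrix(gi, nrow = nrow(values))
}

#' Extract the region-of-interest cells of a frame
#'
#' @param frame Numeric (temperature) or integer (gray) matrix.
#' @param mask Logical matrix of the same dimensions.
#' @return A list with `values` (the in-ROI cells, column-scan order) and
#'   `positions` (two-column matrix of 0-based `row`, `col` coordinates,
#'   origin top-left).
#' @export
extract_roi <- function(frame, mask) {
  if (!identical(dim(frame), dim(mask))) {
    abort(sprintf(
      "frame is %dx%d but mask is %dx%d",
      nrow(frame), ncol(frame), nrow(mask), ncol(mask)
    ))
  }
  idx <- which(mask)
  if (length(idx) == 0L) abort("empty ROI")
  pos <- arrayInd(idx, dim(mask)) - 1L
  colnames(pos) <- c("row", "col")
  list(values = frame[idx], positions = pos)
}
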