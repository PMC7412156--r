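#' Higuchi sub-series of a feature trajectory
#'
#' From a series `x(0), ..., x(N-1)` (0-based), the sub-series for
#' decimation interval `k` and offset `m` keeps the elements at indices
#' `m, m + k, m + 2k, ...` below `N`, in order. The `k` sub-series for a
#' given interval partition the original index set, so coarser views of a
#' feature trajectory are obtained without discarding information overall.
#'
#' @param series Numeric vector (a phase-1 feature trajectory).
#' @param k Decimation interval, `1..4`.
#' @param m Offset, `0..k-1`.
#' @return Numeric vector of the decimated series.
#' @export
subseries <- function(series, k, m) {
  if (length(series) == 0L) abort("empty series")
  if (k < 1L || k > 4L) abort("`k` must be in 1..4")
  if (m < 0L || m >= k) abort("`m` must satisfy 0 <= m < k")
  idx <- seq.int(m, length(series) - 1L, by = k)
  series[idx + 1L]
}

#' Enumerate all (k, m) sub-series configurations
#'
#' @param k_max Largest decimation interval (default 4, giving the 10
#'   standard configurations).
#' @return Tibble with columns `k` and `m`, ordered by `k` then `m`.
#' @export
enumerate_configurations <- function(k_max = 4L) {
  if (k_max < 1L) abort("`k_max` must be at least 1")
  purrr::map_dfr(seq_len(k_max), function(k) {
    tibble::tibble(k = k, m = 0:(k - 1L))
  })
}

#' Higuchi normalized curve length of a sub-series
#'
#' The absolute-increment sum of the decimated series, normalized for the
#' decimation: `L(m, k) = (sum_{i=1}^{I} |x(m + i k) - x(m + (i-1) k)|) *
#' (N - 1) / (I * k) / k` with `I = floor((N - 1 - m) / k)` so that every
#' index stays inside the 0-based series. Provided for completeness as part
#' of the sub-series machinery; the classification features are the range
#' and RMS, not the curve length.
#'
#' @param series Numeric vector of length `N`.
#' @inheritParams subseries
#' @return Scalar normalized curve length.
#' @export
higuchi_length <- function(series, k, m) {
  n <- length(series)
  if (k < 1L) abort("`k` must be at least 1")
  if (m < 0L || m >= k) abort("`m` must satisfy 0 <= m < k")
  imax <- floor((n - 1L - m) / k)
  if (imax < 1L) abort("sub-series too short for a curve length")
  x <- series[m + (0:imax) * k + 1L]
  sum(abs(diff(x))) * (n - 1) / (imax * k) / k
}

#' Range (amplitude) of a sub-series
#'
#' `R = max(x) - min(x)`: how far the feature travels over the exam. For
#' temperature-based features this captures the depth of the post-cooling
#' recovery, which tumor-bearing breasts tend to blunt.
#'
#' @param x Numeric vector.
#' @return Non-negative scalar.
#' @export
range_feature <- function(x) {
  if (length(x) == 0L) abort("empty sub-series")
  max(x) - min(x)
}

#' Root mean square (M2) of a sub-series
#'
#' `M2 = sqrt(sum(x^2) / n)`, the square root of the series' second moment
#' about zero: the overall magnitude of the feature over the exam.
#'
#' @param x Numeric vector.
#' @return Non-negative scalar; equals `|c|` for a constant series `c`.
#' @export
m2_feature <- function(x) {
  if (length(x) == 0L) abort("empty sub-series")
  sqrt(sum(x^2) / length(x))
}

#' Build the per-breast feature matrix for one (k, m) configuration
#'
#' For every phase-1 feature `F`, its trajectory for each breast is
#' decimated with [subseries()] and summarised by two phase-2 scalars:
#' column `"R F"` is the sub-series RMS ([m2_feature()]) and column
#' `"A F"` its amplitude ([range_feature()]). (The R/A prefixes follow the
#' reporting convention of the screening literature this implements: R for
#' the root of the second moment, A for amplitude.)
#'
#' @param features_tbl Long tibble from [extract_cohort_features()] (or
#'   [extract_frame_features()]), with columns `breast_id`, `label`,
#'   `feature`, `step`, `value`.
#' @param k,m Sub-series configuration.
#' @return Wide tibble: `breast_id`, `label`, then `"R <feature>"` and
#'   `"A <feature>"` columns in canonical feature order.
#' @export
build_feature_matrix <- function(features_tbl, k = 4L, m = 0L) {
  feats <- unique(features_tbl$feature)
  per_breast <- features_tbl |>
    dplyr::group_by(.data$breast_id, .data$label, .data$feature) |>
    dplyr::arrange(.data$step, .by_group = TRUE) |>
    dplyr::summarise(
      r = m2_feature(subseries(.data$value, k, m)),
      a = range_feature(subseries(.data$value, k, m)),
      .groups = "drop"
    )
  counts <- per_breast |>
    dplyr::count(.data$breast_id) |>
    dplyr::pull(.data$n)
  if (length(unique(counts)) > 1L) {
    abort("breasts carry inconsistent phase-1 feature sets")
  }
  wide <- per_breast |>
    tidyr::pivot_longer(c("r", "a"), names_to = "stat", values_to = "value") |>
    dplyr::mutate(
      column = paste(ifelse(.data$stat == "r", "R", "A"), .data$feature)
    ) |>
    dplyr::select("breast_id", "label", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  ordered_cols <- as.vector(rbind(
    paste("R", intersect(frame_feature_names(), feats)),
    paste("A", intersect(frame_feature_names(), feats))
  ))
  ordered_cols <- ordered_cols[ordered_cols %in% names(wide)]
  out <- wide[, c("breast_id", "label", ordered_cols)]
  if (any(!vapply(out[ordered_cols], function(x) all(is.finite(x)), logical(1)))) {
    abort("non-finite value in feature matrix")
  }
  out
}
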