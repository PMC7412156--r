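#' Read a radiometric temperature array from a text grid
#'
#' Temperature arrays are plain-text exports of a thermogram: one row of
#' decimal degrees-Celsius values per image row, whitespace- or
#' semicolon-delimited (exports from radiometric tooling vary). The grid is
#' returned as a numeric matrix in row-major image orientation (origin
#' top-left).
#'
#' @param path Path to the text grid.
#' @param delimiter Field delimiter: `"auto"` (default; semicolon if the
#'   first line contains one, otherwise any whitespace), `"whitespace"`,
#'   or a literal single-character delimiter such as `";"`.
#' @param frame_index Optional 0-based position of this frame in its exam
#'   sequence, stored as an attribute.
#' @return A numeric matrix of temperatures in degrees Celsius with
#'   attribute `frame_index`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("30.1 30.2", "29.9 30.0"), f)
#' read_temperature_array(f)
#' @export
read_temperature_array <- function(path, delimiter = "auto", frame_index = 0L) {
  if (!file.exists(path)) {
    abort(sprintf("temperature array not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("empty temperature array: %s", path))
  }
  if (identical(delimiter, "auto")) {
    delimiter <- if (grepl(";", lines[[1]], fixed = TRUE)) ";" else "whitespace"
  }
  split_row <- function(line) {
    if (identical(delimiter, "whitespace")) {
      tok <- strsplit(trimws(line), "\\s+")[[1]]
    } else {
      tok <- strsplit(line, delimiter, fixed = TRUE)[[1]]
    }
    tok[nzchar(trimws(tok))]
  }
  rows <- lapply(lines, split_row)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[[1]])[[1]]
    abort(sprintf(
      "ragged temperature array %s: line %d has %d columns, expected %d",
      path, bad, widths[[bad]], widths[[1]]
    ))
  }
  vals <- suppressWarnings(vapply(unlist(rows), as.numeric, numeric(1)))
  if (anyNA(vals)) {
    bad_tok <- unlist(rows)[which(is.na(vals))[[1]]]
    abort(sprintf("non-numeric token '%s' in temperature array %s", bad_tok, path))
  }
  values <- matrix(vals, nrow = length(rows), byrow = TRUE)
  if (!all(is.finite(values))) {
    abort(sprintf("non-finite temperature in %s", path))
  }
  if (any(values < 15 | values > 45)) {
    warn(sprintf("temperatures outside the physiologic range [15, 45] degC in %s", path))
  }
  attr(values, "frame_index") <- as.integer(frame_index)
  values
}

#' Write a temperature array as a text grid
#'
#' @param values Numeric matrix of temperatures (degrees Celsius).
#' @param path Output path.
#' @param delimiter Field separator written between values (default one space).
#' @param digits Decimal digits to print (default 3; radiometric exports carry
#'   centidegree precision at best given camera sensitivity < 0.04 degC).
#' @return `path`, invisibly.
#' @export
write_temperature_array <- function(values, path, delimiter = " ", digits = 3L) {
  stopifnot_matrix(values, "values")
  lines <- apply(values, 1L, function(r) {
    paste(formatC(r, format = "f", digits = digits), collapse = delimiter)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary region-of-interest mask
#'
#' Masks delimit the breast region of a frame. PNG and PGM (both plain `P2`
#' and binary `P5`) files are accepted; any nonzero pixel is inside the ROI.
#'
#' @param path Path to a PNG or PGM image.
#' @return A logical matrix (`TRUE` = inside ROI).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("mask not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3L) x <- x[, , 1L]
      x
    },
    pgm = read_pgm(path),
    abort(sprintf("unsupported mask format '%s' (PNG or PGM expected): %s", ext, path))
  )
  mask <- img != 0
  if (!any(mask)) {
    abort(sprintf("empty mask (no nonzero pixel): %s", path))
  }
  mask
}

#' Write a binary mask as a plain-text PGM (P2) image
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param path Output path (`.pgm`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix")
  m <- matrix(as.integer(mask != 0) * 255L, nrow = nrow(mask))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}

# Minimal PGM reader: plain (P2) and raw 8-bit (P5).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    abort(sprintf("not a PGM file (magic '%s'): %s", magic, path))
  }
  # header tokens: width, height, maxval; '#' starts a comment
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") abort(sprintf("truncated PGM header: %s", path))
    if (ch == "#") {
      repeat {
        ch2 <- rawToChar(readBin(con, "raw", 1L))
        if (ch2 %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  width <- tokens[[1]]; height <- tokens[[2]]; maxval <- tokens[[3]]
  n <- width * height
  if (magic == "P5") {
    if (maxval > 255L) abort("16-bit P5 PGM not supported")
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(rest), "\\s+")[[1]])
  }
  if (length(vals) < n) abort(sprintf("truncated PGM data: %s", path))
  matrix(vals[seq_len(n)], nrow = height, byrow = TRUE)
}

#' Assemble a thermal sequence for one breast
#'
#' @param breast_id Unique identifier.
#' @param label `"healthy"` or `"sick"`.
#' @param frames List of temperature matrices, in acquisition order.
#' @param masks List of logical ROI masks, one per frame.
#' @return A `thermal_sequence` object.
#' @export
thermal_sequence <- function(breast_id, label, frames, masks) {
  if (length(frames) != length(masks)) {
    abort(sprintf(
      "breast %s: %d frames but %d masks", breast_id, length(frames), length(masks)
    ))
  }
  if (length(frames) == 0L) abort("a thermal sequence needs at least one frame")
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), dim(masks[[i]]))) {
      abort(sprintf("breast %s frame %d: frame/mask dimension mismatch", breast_id, i - 1L))
    }
    if (!any(masks[[i]])) abort(sprintf("breast %s frame %d: empty mask", breast_id, i - 1L))
  }
  structure(
    list(
      breast_id = as.character(breast_id),
      label = match.arg(label, c("healthy", "sick")),
      frames = frames,
      masks = masks
    ),
    class = "thermal_sequence"
  )
}

#' @export
print.thermal_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<thermal_sequence> breast %s (%s): %d frames of %dx%d\n",
    x$breast_id, x$label, length(x$frames), d[1], d[2]
  ))
  invisible(x)
}

#' Build a cohort from in-memory sequences
#'
#' @param sequences List of [thermal_sequence()] objects.
#' @param provenance Free-text metadata string.
#' @return A `thermal_cohort` object.
#' @export
thermal_cohort <- function(sequences, provenance = "") {
  ids <- vapply(sequences, function(s) s$breast_id, character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate breast_id in cohort: %s", ids[duplicated(ids)][[1]]))
  }
  structure(
    list(sequences = sequences, provenance = provenance),
    class = "thermal_cohort"
  )
}

#' @export
print.thermal_cohort <- function(x, ...) {
  labs <- vapply(x$sequences, function(s) s$label, character(1))
  cat(sprintf(
    "<thermal_cohort> %d breasts (%d healthy, %d sick), %d frames total\n",
    length(x$sequences), sum(labs == "healthy"), sum(labs == "sick"),
    sum(vapply(x$sequences, function(s) length(s$frames), integer(1)))
  ))
  invisible(x)
}

#' Load a cohort from a manifest file
#'
#' The manifest maps breasts to their ordered frame and mask files. Two
#' formats are accepted, chosen by extension:
#' * CSV with columns `breast_id`, `label`, `frame_index`, `frame_path`,
#'   `mask_path` (one row per frame);
#' * JSON: an array of objects with fields `breast_id`, `label`, `frames`,
#'   `masks` (the latter two are arrays of paths in order).
#'
#' Paths are resolved relative to the manifest's directory.
#'
#' @param manifest Path to the manifest file.
#' @param delimiter Delimiter spec forwarded to [read_temperature_array()].
#' @return A `thermal_cohort`.
#' @export
load_cohort <- function(manifest, delimiter = "auto") {
  if (!file.exists(manifest)) abort(sprintf("manifest not found: %s", manifest))
  base <- dirname(normalizePath(manifest))
  ext <- tolower(tools::file_ext(manifest))
  if (ext == "json") {
    entries <- jsonlite::fromJSON(manifest, simplifyVector = FALSE)
    rows <- purrr::map_dfr(entries, function(e) {
      tibble::tibble(
        breast_id = e$breast_id, label = e$label,
        frame_index = seq_along(e$frames) - 1L,
        frame_path = unlist(e$frames), mask_path = unlist(e$masks)
      )
    })
  } else {
    rows <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
    needed <- c("breast_id", "label", "frame_index", "frame_path", "mask_path")
    if (!all(needed %in% names(rows))) {
      abort(sprintf(
        "manifest %s lacks columns: %s", manifest,
        paste(setdiff(needed, names(rows)), collapse = ", ")
      ))
    }
  }
  if (anyDuplicated(paste(rows$breast_id, rows$frame_index))) {
    abort("manifest repeats a (breast_id, frame_index) pair")
  }
  seqs <- rows |>
    dplyr::arrange(.data$breast_id, .data$frame_index) |>
    dplyr::group_by(.data$breast_id) |>
    dplyr::group_map(function(g, key) {
      if (dplyr::n_distinct(g$label) != 1L) {
        abort(sprintf("breast %s has conflicting labels", key$breast_id))
      }
      frames <- purrr::map2(g$frame_path, g$frame_index, function(p, i) {
        read_temperature_array(file.path(base, p), delimiter = delimiter, frame_index = i)
      })
      masks <- purrr::map(g$mask_path, function(p) read_mask(file.path(base, p)))
      thermal_sequence(key$breast_id, g$label[[1]], frames, masks)
    })
  thermal_cohort(seqs, provenance = manifest)
}

#' Write a cohort to disk in manifest + text-grid + PGM layout
#'
#' Writes one text grid and one PGM mask per frame under `dir`, plus a
#' `manifest.csv` that [load_cohort()] reads back.
#'
#' @param cohort A `thermal_cohort`.
#' @param dir Output directory (created if needed).
#' @param digits Decimal digits for the temperature grids.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, digits = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(cohort$sequences, function(s) {
    purrr::map_dfr(seq_along(s$frames), function(i) {
      fp <- sprintf("%s_frame%02d.txt", s$breast_id, i - 1L)
      mp <- sprintf("%s_mask%02d.pgm", s$breast_id, i - 1L)
      write_temperature_array(s$frames[[i]], file.path(dir, fp), digits = digits)
      write_mask(s$masks[[i]], file.path(dir, mp))
      tibble::tibble(
        breast_id = s$breast_id, label = s$label, frame_index = i - 1L,
        frame_path = fp, mask_path = mp
      )
    })
  })
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(rows, manifest, progress = FALSE)
  invisible(manifest)
}

#' Read or write a per-breast feature table
#'
#' Feature tables hold one breast per row: `breast_id`, a `label` column,
#' and one numeric column per feature. CSV with a header row.
#'
#' @param matrix_tbl Tibble with columns `breast_id`, `label`, features.
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(matrix_tbl, path) {
  if (anyDuplicated(names(matrix_tbl))) abort("duplicate column names in feature table")
  readr::write_csv(matrix_tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("feature table not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(tbl)) tbl$label <- as.character(tbl$label)
  tbl
}
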