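#' @keywords internal
#' @importFrom rlang abort warn .data
"_PACKAGE"

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG alone.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopifnot_matrix <- function(x, what = "values") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix", what))
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort(sprintf("`%s` must have positive dimensions", what))
  }
  invisible(x)
}

# Column names of a feature matrix tibble that hold features (not metadata).
feature_columns <- function(matrix_tbl) {
  setdiff(names(matrix_tbl), c("breast_id", "label"))
}

check_label <- function(label) {
  if (!all(label %in% c("healthy", "sick"))) {
    abort("labels must be 'healthy' or 'sick'")
  }
  factor(label, levels = c("healthy", "sick"))
}
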