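#' Fit and apply [0, 1] normalization bounds
#'
#' Each feature column is rescaled as `Y = (X - Xmin) / (Xmax - Xmin)` with
#' the bounds taken over the fitted sample, so no attribute's numeric range
#' dominates the SVM kernel. Constant columns map to 0; values outside the
#' fitted range at apply time (new exams) clip to `[0, 1]`.
#'
#' @param matrix_tbl Feature-matrix tibble (`breast_id`, `label`, features).
#' @return `fit_bounds()`: a `norm_bounds` object (per-column min/max);
#'   `apply_bounds()`: the rescaled tibble.
#' @export
fit_bounds <- function(matrix_tbl) {
  cols <- feature_columns(matrix_tbl)
  if (length(cols) == 0L || nrow(matrix_tbl) == 0L) abort("empty feature matrix")
  structure(
    list(
      min = vapply(matrix_tbl[cols], min, numeric(1)),
      max = vapply(matrix_tbl[cols], max, numeric(1))
    ),
    class = "norm_bounds"
  )
}

#' @rdname fit_bounds
#' @param bounds A `norm_bounds` from [fit_bounds()].
#' @export
apply_bounds <- function(matrix_tbl, bounds) {
  cols <- names(bounds$min)
  out <- matrix_tbl
  for (cn in cols) {
    rng <- bounds$max[[cn]] - bounds$min[[cn]]
    y <- if (rng > 0) (matrix_tbl[[cn]] - bounds$min[[cn]]) / rng else rep(0, nrow(matrix_tbl))
    out[[cn]] <- pmin(pmax(y, 0), 1)
  }
  out
}

# |Pearson correlation|, with 0 for zero-variance inputs.
abs_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(x, y))
}

#' CFS merit of a feature subset
#'
#' Correlation-based feature selection scores a subset of `s` features as
#' `merit = s * rcf / sqrt(s + s * (s - 1) * rff)`, where `rcf` is the mean
#' absolute Pearson correlation of the subset's features with the 0/1 class
#' label and `rff` the mean absolute pairwise correlation within the
#' subset: subsets that predict the class while being mutually redundant
#' score low. Zero-variance features contribute correlation 0.
#'
#' @param subset Character vector of feature column names.
#' @param matrix_tbl Feature-matrix tibble.
#' @param labels Class labels (`"healthy"`/`"sick"`), taken from the
#'   matrix's `label` column when `NULL`.
#' @return Scalar merit (equals `rcf` for a single feature).
#' @export
cfs_merit <- function(subset, matrix_tbl, labels = NULL) {
  if (length(subset) == 0L) abort("empty subset")
  if (is.null(labels)) labels <- matrix_tbl$label
  y <- as.numeric(check_label(labels)) - 1
  s <- length(subset)
  rcf <- mean(vapply(subset, function(f) abs_cor(matrix_tbl[[f]], y), numeric(1)))
  rff <- 0
  if (s > 1L) {
    pairs <- utils::combn(subset, 2L)
    rff <- mean(apply(pairs, 2L, function(p) {
      abs_cor(matrix_tbl[[p[1]]], matrix_tbl[[p[2]]])
    }))
  }
  s * rcf / sqrt(s + s * (s - 1) * rff)
}

#' Best-first forward search over CFS merit
#'
#' Greedy best-first search from the empty set: the open list holds
#' candidate subsets ordered by merit; the best subset is expanded by
#' adding each unused feature; the search stops after `stale_limit`
#' consecutive expansions that fail to improve the best merit seen. Ties
#' break by column order, so the result is deterministic.
#'
#' @param matrix_tbl Feature-matrix tibble.
#' @param labels Optional labels (default: the `label` column).
#' @param stale_limit Consecutive non-improving expansions tolerated.
#' @return Character vector of selected feature names (column order), with
#'   the achieved merit as attribute `"merit"`.
#' @export
best_first_select <- function(matrix_tbl, labels = NULL, stale_limit = 5L) {
  cols <- feature_columns(matrix_tbl)
  if (length(cols) == 0L) abort("no features to select from")
  if (is.null(labels)) labels <- matrix_tbl$label
  key <- function(sub) paste(sort(match(sub, cols)), collapse = ",")
  open <- list(list(sub = character(0), merit = -Inf))
  visited <- new.env(parent = emptyenv())
  best_sub <- character(0)
  best_merit <- -Inf
  stale <- 0L
  while (length(open) > 0L && stale < stale_limit) {
    merits <- vapply(open, function(n) n$merit, numeric(1))
    pick <- which.max(merits)  # first max: deterministic tie-break
    node <- open[[pick]]
    open <- open[-pick]
    improved <- FALSE
    for (f in setdiff(cols, node$sub)) {
      child <- c(node$sub, f)
      k <- key(child)
      if (!is.null(visited[[k]])) next
      assign(k, TRUE, envir = visited)
      merit <- cfs_merit(child, matrix_tbl, labels)
      open <- c(open, list(list(sub = child, merit = merit)))
      if (merit > best_merit + 1e-12) {
        best_merit <- merit
        best_sub <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  out <- cols[sort(match(best_sub, cols))]
  attr(out, "merit") <- best_merit
  out
}

#' SVM configuration
#'
#' Radial-basis-function support vector classification in either the C or
#' the nu formulation, with the defaults of the standard libsvm tooling:
#' `C = 1`, `nu = 0.5`, `gamma = 1 / n_features`, shrinking on, termination
#' tolerance `1e-3`.
#'
#' @param formulation `"C-SVC"` or `"Nu-SVC"`.
#' @param C Cost for C-SVC.
#' @param nu Nu for Nu-SVC.
#' @param gamma RBF width; `NULL` means `1 / n_features` at fit time.
#' @param seed Integer seed (libsvm training is deterministic for
#'   classification; kept for interface stability).
#' @return An `svm_config` list.
#' @export
svm_config <- function(formulation = c("C-SVC", "Nu-SVC"), C = 1, nu = 0.5,
                       gamma = NULL, seed = 1L) {
  formulation <- match.arg(formulation)
  if (C <= 0) abort("C must be positive")
  if (nu <= 0 || nu >= 1) abort("nu must lie in (0, 1)")
  if (!is.null(gamma) && gamma <= 0) abort("gamma must be positive")
  structure(
    list(formulation = formulation, C = C, nu = nu, gamma = gamma, seed = seed),
    class = "svm_config"
  )
}

fit_svm <- function(x, y, config) {
  type <- if (config$formulation == "C-SVC") "C-classification" else "nu-classification"
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  e1071::svm(
    x = x, y = y, type = type, kernel = "radial",
    cost = config$C, nu = config$nu, gamma = gamma,
    scale = FALSE, shrinking = TRUE, tolerance = 1e-3
  )
}

#' Classification metrics from a confusion table
#'
#' Sick is the positive class. Sensitivity `= TP / (TP + FN)`, specificity
#' `= TN / (TN + FP)` and accuracy are reported as percentages; Youden's
#' index `= sensitivity + specificity - 1` on the unit scale. Two areas are
#' reported: `auc_balanced`, the discrete-prediction ROC area
#' `(sens + spec) / 2`, and `roc_acc_scale = accuracy / 100`, the
#' accuracy restated on the unit scale as some screening reports print it.
#'
#' @param tp,fp,tn,fn Aggregated confusion counts.
#' @return One-row tibble of metrics.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0) || tp + fp + tn + fn == 0) {
    abort("confusion counts must be non-negative with a positive total")
  }
  if (tp + fn == 0) abort("no positive (sick) cases: sensitivity undefined")
  if (tn + fp == 0) abort("no negative (healthy) cases: specificity undefined")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / (tp + fp + tn + fn)
  tibble::tibble(
    sensitivity = sens, specificity = spec, accuracy = acc,
    youden = sens / 100 + spec / 100 - 1,
    auc_balanced = (sens / 100 + spec / 100) / 2,
    roc_acc_scale = acc / 100,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Leave-one-out evaluation of the RBF-SVM screening classifier
#'
#' Each breast is held out once; the classifier is trained on the rest and
#' predicts the held-out breast; the confusion table aggregates over all
#' folds. By default normalization bounds and the CFS-selected subset are
#' fitted once on the full matrix before the loop (the protocol that makes
#' per-configuration subsets reportable); `fold_safe = TRUE` refits both
#' inside every fold — the leakage-free variant, at the cost of a possibly
#' different subset per fold.
#'
#' @param matrix_tbl Feature-matrix tibble from [build_feature_matrix()].
#' @param config An [svm_config()].
#' @param select Run CFS best-first feature selection first?
#' @param fold_safe Refit normalization and selection within each fold.
#' @param k,m Sub-series configuration the matrix came from (metadata).
#' @return A `dit_eval` object: metrics tibble, confusion counts, selected
#'   features, per-breast predictions, and the configuration.
#' @export
loocv_evaluate <- function(matrix_tbl, config = svm_config(), select = TRUE,
                           fold_safe = FALSE, k = NA_integer_, m = NA_integer_) {
  labels <- check_label(matrix_tbl$label)
  if (any(table(labels) < 2L)) abort("need at least 2 breasts per class")
  n <- nrow(matrix_tbl)
  selected <- feature_columns(matrix_tbl)
  if (select && !fold_safe) {
    selected <- as.character(best_first_select(matrix_tbl))
  }
  if (!fold_safe) {
    bounds <- fit_bounds(matrix_tbl)
    norm <- apply_bounds(matrix_tbl, bounds)
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    if (fold_safe) {
      train_raw <- matrix_tbl[-i, ]
      sel_i <- if (select) as.character(best_first_select(train_raw)) else selected
      bounds_i <- fit_bounds(train_raw)
      train <- apply_bounds(train_raw, bounds_i)
      test <- apply_bounds(matrix_tbl[i, ], bounds_i)
    } else {
      sel_i <- selected
      train <- norm[-i, ]
      test <- norm[i, ]
    }
    fit <- fit_svm(
      as.matrix(train[sel_i]), droplevels(factor(labels[-i], levels = levels(labels))),
      config
    )
    pred[[i]] <- as.character(stats::predict(fit, as.matrix(test[sel_i])))
  }
  truth <- as.character(labels)
  tp <- sum(pred == "sick" & truth == "sick")
  tn <- sum(pred == "healthy" & truth == "healthy")
  fp <- sum(pred == "sick" & truth == "healthy")
  fn <- sum(pred == "healthy" & truth == "sick")
  structure(
    list(
      metrics = compute_metrics(tp, fp, tn, fn),
      predictions = tibble::tibble(
        breast_id = matrix_tbl$breast_id, truth = truth, predicted = pred
      ),
      selected = selected,
      k = k, m = m,
      formulation = config$formulation,
      select = select, fold_safe = fold_safe
    ),
    class = "dit_eval"
  )
}

#' @export
print.dit_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<dit_eval> %s%s k=%s m=%s\n  sens %.2f%%  spec %.2f%%  acc %.2f%%  Youden %.2f\n  %d selected feature(s): %s\n",
    x$formulation, if (x$fold_safe) " (fold-safe)" else "",
    x$k, x$m, m$sensitivity, m$specificity, m$accuracy, m$youden,
    length(x$selected), paste(x$selected, collapse = "; ")
  ))
  invisible(x)
}
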