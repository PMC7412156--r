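make_matrix <- function(n = 20L, p = 4L, seed = 1L, informative = NULL) {
  set.seed(seed)
  label <- rep(c("healthy", "sick"), length.out = n)
  cols <- stats::setNames(lapply(seq_len(p), function(i) rnorm(n)),
                          paste0("f", seq_len(p)))
  tbl <- tibble::tibble(breast_id = sprintf("b%02d", seq_len(n)),
                        label = label, !!!cols)
  if (!is.null(informative)) {
    tbl[[informative]] <- (label == "sick") * 2 + rnorm(n, sd = 0.1)
  }
  tbl
}

test_that("unit-interval normalization follows the min-max rule", {
  tbl <- tibble::tibble(breast_id = c("a", "b", "c"),
                        label = c("healthy", "sick", "healthy"),
                        x = c(2, 4, 6), const = c(5, 5, 5))
  b <- fit_bounds(tbl)
  norm <- apply_bounds(tbl, b)
  expect_equal(norm$x, c(0, 0.5, 1))
  expect_equal(norm$const, c(0, 0, 0))

  # out-of-range values at apply time clip to [0, 1]
  new <- tibble::tibble(breast_id = "d", label = "sick", x = 10, const = 7)
  expect_equal(apply_bounds(new, b)$x, 1)

  mt <- make_matrix(30L, 5L, seed = 8L)
  nm <- apply_bounds(mt, fit_bounds(mt))
  for (cn in paste0("f", 1:5)) {
    expect_true(all(nm[[cn]] >= 0 & nm[[cn]] <= 1))
    expect_equal(min(nm[[cn]]), 0)
    expect_equal(max(nm[[cn]]), 1)
  }
})

test_that("CFS merit matches its closed form and a brute-force oracle", {
  mt <- make_matrix(40L, 6L, seed = 3L, informative = "f1")
  y <- as.integer(mt$label == "sick")
  expect_equal(cfs_merit("f1", mt), abs(cor(mt$f1, y)), tolerance = 1e-12)

  # a duplicated feature can never beat the feature alone
  mt$dup <- mt$f1
  expect_lte(cfs_merit(c("f1", "dup"), mt), cfs_merit("f1", mt) + 1e-12)

  # zero-variance feature has correlation 0 by definition
  mt$flat <- 1
  expect_equal(cfs_merit("flat", mt), 0)

  for (seed in 1:4) {
    m2 <- make_matrix(25L, 5L, seed = seed)
    y2 <- as.integer(m2$label == "sick")
    for (sub in list("f2", c("f1", "f3"), c("f1", "f2", "f4", "f5"))) {
      expect_equal(cfs_merit(sub, m2), oracle_cfs_merit(sub, m2, y2),
                   tolerance = 1e-9)
    }
  }
})

test_that("best-first search finds the informative feature and the exhaustive optimum", {
  mt <- make_matrix(40L, 10L, seed = 5L, informative = "f3")
  sel <- best_first_select(mt)
  expect_true("f3" %in% sel)

  # on pure noise the achievable merit stays near zero and far below the
  # merit of a genuinely informative subset
  noise <- make_matrix(200L, 8L, seed = 6L)
  sel_noise <- best_first_select(noise)
  expect_lt(attr(sel_noise, "merit"), 0.25)
  expect_gt(attr(best_first_select(mt), "merit"), 3 * attr(sel_noise, "merit"))

  # exhaustive enumeration over all 2^6 - 1 subsets agrees on the merit
  small <- make_matrix(30L, 6L, seed = 7L, informative = "f2")
  subsets <- unlist(lapply(1:6, function(s) {
    asplit(utils::combn(paste0("f", 1:6), s), 2L)
  }), recursive = FALSE)
  merits <- vapply(subsets, function(s) cfs_merit(as.character(s), small), numeric(1))
  bf <- best_first_select(small)
  expect_equal(attr(bf, "merit"), max(merits), tolerance = 1e-9)
})

test_that("confusion-table metrics reproduce the standard screening rates", {
  # 31 sick all found, 33 healthy with one false alarm
  m <- compute_metrics(tp = 31, fp = 1, tn = 32, fn = 0)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 96.97, tolerance = 1e-4)
  expect_equal(round(m$youden, 2), 0.97)

  m2 <- compute_metrics(tp = 10, fp = 1, tn = 9, fn = 0)
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 90)
  expect_equal(m2$accuracy, 95)
  expect_equal(m2$youden, 0.9)

  m3 <- compute_metrics(tp = 12, fp = 0, tn = 11, fn = 0)
  expect_equal(m3$youden, 1)
  expect_equal(m3$accuracy, 100)
  expect_equal(m3$roc_acc_scale, 1)

  expect_error(compute_metrics(0, 1, 3, 0), "sensitivity undefined")
})

test_that("leave-one-out evaluation separates separable classes and not permuted ones", {
  n <- 24L
  set.seed(17)
  sep <- tibble::tibble(
    breast_id = sprintf("b%02d", 1:n),
    label = rep(c("healthy", "sick"), each = n / 2),
    x = c(rnorm(n / 2, -2, 0.3), rnorm(n / 2, 2, 0.3)),
    y = rnorm(n)
  )
  ev <- loocv_evaluate(sep, select = FALSE)
  expect_equal(ev$metrics$accuracy, 100)
  expect_equal(ev$metrics$accuracy,
               100 * (ev$metrics$tp + ev$metrics$tn) / n)

  m <- 40L
  set.seed(23)
  null <- tibble::tibble(
    breast_id = sprintf("b%02d", 1:m),
    label = sample(rep(c("healthy", "sick"), each = m / 2)),
    x = rnorm(m), y = rnorm(m)
  )
  evn <- loocv_evaluate(null, select = FALSE)
  half_ci <- 100 * 1.96 * sqrt(0.25 / m)
  expect_gte(evn$metrics$accuracy, 50 - half_ci)
  expect_lte(evn$metrics$accuracy, 50 + half_ci)
})

test_that("both SVM formulations and the fold-safe protocol run end to end", {
  mt <- make_matrix(30L, 5L, seed = 29L, informative = "f1")
  ev_nu <- loocv_evaluate(mt, config = svm_config("Nu-SVC"), select = TRUE)
  expect_gte(ev_nu$metrics$accuracy, 80)
  expect_identical(ev_nu$formulation, "Nu-SVC")

  ev_fs <- loocv_evaluate(mt, select = TRUE, fold_safe = TRUE)
  expect_gte(ev_fs$metrics$accuracy, 80)

  g <- glance(ev_nu)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("sensitivity", "specificity", "accuracy", "youden",
                    "n_selected") %in% names(g)))
  td <- tidy(ev_nu)
  expect_identical(nrow(td), 5L)

  expect_error(svm_config(C = -1), "positive")
  expect_error(svm_config(nu = 1.5), "nu")
})

test_that("classification is invariant to affine rescaling of an input column", {
  mt <- make_matrix(26L, 4L, seed = 31L, informative = "f2")
  ev1 <- loocv_evaluate(mt, select = FALSE)
  mt2 <- mt
  mt2$f2 <- 1000 * mt2$f2 - 40  # same information, different scale
  ev2 <- loocv_evaluate(mt2, select = FALSE)
  expect_identical(ev1$predictions$predicted, ev2$predictions$predicted)
})
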