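test_that("mean and population standard deviation match a two-pass oracle", {
  expect_equal(mean_std(c(30, 30, 30)), c(mean = 30, std = 0))
  expect_equal(mean_std(c(1, 3)), c(mean = 2, std = 1))
  set.seed(2)
  x <- runif(1000, 25, 40)
  got <- mean_std(x)
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / length(x))
  expect_equal(unname(got), c(m, s), tolerance = 1e-9)
  expect_error(mean_std(numeric(0)), "empty")
})

test_that("1-D k-means converges monotonically and finds cluster structure", {
  expect_equal(grouping(rep(30, 20), n_clusters = 3L, seed = 1L), 30)

  set.seed(4)
  x <- c(rnorm(200, 28, 0.01), rnorm(200, 35, 0.01))
  km <- kmeans1d(x, n_clusters = 2L, seed = 1L)
  expect_lt(abs(max(km$centroids) - 35), 0.05)
  expect_true(all(diff(km$sqres_trace) <= 1e-9))

  # permutation invariance of the result given the same seeded init draw
  set.seed(10)
  y <- runif(300, 20, 40)
  g1 <- grouping(y, seed = 99L)
  g2 <- grouping(sample(y), seed = 99L)
  expect_equal(g1, g2, tolerance = 0.2)

  # independent cross-check on well-separated data: stats::kmeans agrees
  ref <- sort(stats::kmeans(x, centers = c(28, 35))$centers[, 1])
  expect_equal(sort(km$centroids), unname(ref), tolerance = 0.01)

  expect_error(kmeans1d(1:5, n_clusters = 9L), "at least 9")
})

test_that("gray histograms count ROI pixels only and conserve mass", {
  expect_equal(gray_histogram(rep(7L, 10))[8], 10)
  expect_equal(sum(gray_histogram(rep(7L, 10))), 10)

  rg <- random_gray_roi(12L, 12L, seed = 21L)
  roi <- extract_roi(rg$gray, rg$mask)
  expect_identical(gray_histogram(roi$values), oracle_gray_hist(roi$values))
  expect_equal(sum(gray_histogram(roi$values)), sum(rg$mask))
})

test_that("histogram distances follow their stated formulas", {
  h <- c(3, 1, 0, 6)
  expect_equal(hist_distance(h, h, "bhattacharyya"), 0)
  expect_equal(hist_distance(h, h, "intersection"), 1)
  expect_equal(hist_distance(h, h, "chisquare"), 0)

  p <- c(1, 0); q <- c(0, 1)
  expect_equal(hist_distance(p, q, "bhattacharyya"), 1)
  expect_equal(hist_distance(p, q, "intersection"), 0)
  expect_equal(hist_distance(p, q, "chisquare"), 1)  # zero-p bin skipped

  expect_error(hist_distance(c(1, 2), c(1, 2, 3)), "bin mismatch")
})

test_that("sum/difference histograms count in-ROI pairs for both neighborhoods", {
  g <- matrix(5L, 3, 3)
  msk <- matrix(TRUE, 3, 3)
  sdh <- sum_diff_histograms(g, msk, 1L, 0L)
  expect_equal(sdh$sum_counts[10 + 1], 6)     # all mass at s = 2g
  expect_equal(sdh$diff_counts[0 + 256], 6)   # all mass at d = 0
  expect_equal(sum(sdh$sum_counts), sdh$n_pairs)

  g2 <- matrix(c(10L, 20L), 1, 2)
  one <- sum_diff_histograms(g2, matrix(TRUE, 1, 2), 1L, 0L)
  expect_equal(one$n_pairs, 1L)
  expect_equal(one$sum_counts[30 + 1], 1)
  expect_equal(one$diff_counts[-10 + 256], 1)

  for (seed in 1:3) {
    rg <- random_gray_roi(10L, 14L, seed = seed, mask_frac = 0.7)
    for (d in list(c(1L, 0L), c(0L, 1L))) {
      got <- sum_diff_histograms(rg$gray, rg$mask, d[1], d[2])
      want <- oracle_sum_diff(rg$gray, rg$mask, d[1], d[2])
      expect_identical(got$sum_counts, want$sum_counts)
      expect_identical(got$diff_counts, want$diff_counts)
    }
  }
})

test_that("pair formation requires both pixels inside the ROI", {
  rg <- random_gray_roi(10L, 10L, seed = 31L, mask_frac = 0.6)
  base <- sum_diff_histograms(rg$gray, rg$mask, 1L, 0L)
  # flip out-of-ROI pixel values: histograms must not change
  g2 <- rg$gray
  g2[!rg$mask] <- 255L - g2[!rg$mask]
  again <- sum_diff_histograms(g2, rg$mask, 1L, 0L)
  expect_identical(base$sum_counts, again$sum_counts)
  expect_identical(base$diff_counts, again$diff_counts)
})

test_that("Unser estimators match their definitions and bounds", {
  g <- matrix(9L, 4, 4)
  msk <- matrix(TRUE, 4, 4)
  u <- unser_features(sum_diff_histograms(g, msk, 1L, 0L))
  expect_equal(unname(u[c("contrast", "homogeneity", "entropy", "energy",
                          "variance", "correlation")]),
               c(0, 1, 0, 1, 0, 0))

  # vertical stripes alternating 0/255: horizontal pairs all differ by 255
  stripes <- matrix(rep(c(0L, 255L), length.out = 6 * 6), 6, 6, byrow = TRUE)
  us <- unser_features(sum_diff_histograms(stripes, matrix(TRUE, 6, 6), 1L, 0L))
  expect_equal(unname(us["contrast"]), 255^2)

  for (seed in 4:6) {
    rg <- random_gray_roi(14L, 11L, seed = seed)
    sdh <- sum_diff_histograms(rg$gray, rg$mask, 0L, 1L)
    got <- unser_features(sdh)
    want <- oracle_unser(sdh$sum_counts, sdh$diff_counts)
    expect_equal(got, want, tolerance = 1e-9)
    expect_gt(got[["homogeneity"]], 0); expect_lte(got[["homogeneity"]], 1)
    expect_gt(got[["energy"]], 0); expect_lte(got[["energy"]], 1)
  }
})

test_that("diversity species are 73 + 73 seven-bin groups with textbook limits", {
  rg <- random_gray_roi(12L, 12L, seed = 41L)
  sdh <- sum_diff_histograms(rg$gray, rg$mask, 1L, 0L)
  expect_length(thermoseries:::species_abundances(sdh), 146L)

  # constant image: every pair has s = 2g, d = 0 -> one sum-species and one
  # diff-species each hold half the total abundance
  g <- matrix(100L, 5, 5)
  dv <- diversity_indices(sum_diff_histograms(g, matrix(TRUE, 5, 5), 1L, 0L))
  expect_equal(unname(dv["simpson"]), 0.5)       # two equal species
  expect_equal(unname(dv["berger_parker"]), 0.5)

  # single species: mass concentrated entirely in one species
  single <- structure(
    list(sum_counts = c(12, rep(0, 510)), diff_counts = rep(0, 511),
         dx = 1L, dy = 0L, n_pairs = 12L),
    class = "sum_diff_hist"
  )
  dv1 <- diversity_indices(single)
  expect_equal(unname(dv1["berger_parker"]), 1)
  expect_equal(unname(dv1["simpson"]), 1)
  expect_equal(unname(dv1["mcintosh"]), 0)

  # equal abundance across S species
  S <- 10L
  counts <- rep(0, 511); counts[seq_len(S * 7)] <- 3
  unif <- structure(
    list(sum_counts = counts, diff_counts = rep(0, 511), dx = 1L, dy = 0L,
         n_pairs = sum(counts)),
    class = "sum_diff_hist"
  )
  dvu <- diversity_indices(unif)
  expect_equal(unname(dvu["simpson"]), 1 / S)
  expect_equal(unname(dvu["berger_parker"]), 1 / S)
})

test_that("spatiograms store per-bin counts, means and population covariance", {
  sp <- spatiogram(200L, matrix(c(3L, 7L), 1))
  expect_equal(sp$counts[201], 1)
  expect_equal(sp$mu[201, ], c(3, 7))

  rg <- random_gray_roi(9L, 9L, seed = 51L)
  roi <- extract_roi(rg$gray, rg$mask)
  sp2 <- spatiogram(roi$values, roi$positions)
  expect_equal(sum(sp2$counts), sum(rg$mask))

  two <- spatiogram(c(40L, 40L), rbind(c(0L, 0L), c(0L, 2L)))
  expect_equal(two$mu[41, ], c(0, 1))
  expect_equal(two$sigma[41, , ], matrix(c(0, 0, 0, 1), 2, 2))
})

test_that("spatiogram similarity is 1 for identical inputs, 0 for disjoint, and drops under translation", {
  rg <- random_gray_roi(10L, 10L, seed = 61L)
  roi <- extract_roi(rg$gray, rg$mask)
  sp <- spatiogram(roi$values, roi$positions)
  expect_equal(spatiogram_similarity(sp, sp), 1, tolerance = 1e-9)

  a <- spatiogram(rep(10L, 3), cbind(0:2, 0:2))
  b <- spatiogram(rep(200L, 3), cbind(0:2, 0:2))
  expect_equal(spatiogram_similarity(a, b), 0)

  # translated blob: same histogram, displaced positions
  blob_vals <- rep(c(50L, 60L), each = 6)
  pos <- as.matrix(expand.grid(row = 0:3, col = 0:2))[seq_len(12), ]
  s0 <- spatiogram(blob_vals, pos)
  s_shift <- spatiogram(blob_vals, pos + 2L)
  expect_lt(spatiogram_similarity(s0, s_shift), 1)
  expect_gt(spatiogram_similarity(s0, s0) - spatiogram_similarity(s0, s_shift), 0.01)
})

test_that("gliding-box lacunarity matches brute-force box enumeration", {
  const <- matrix(7L, 10, 12)
  msk <- matrix(TRUE, 10, 12)
  expect_equal(lacunarity(const, msk, window_sizes = c(2L, 4L, 8L)), 1)
  per <- lacunarity(const, msk, window_sizes = c(2L, 4L, 8L), per_size = TRUE)
  expect_equal(unname(per), rep(1, 3))

  spot <- matrix(0L, 8, 8); spot[4, 5] <- 200L
  expect_gt(lacunarity(spot, matrix(TRUE, 8, 8), window_sizes = 2L), 1)

  set.seed(71)
  g <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  m <- matrix(TRUE, 16, 16)
  expect_equal(
    lacunarity(g, m, window_sizes = 4L),
    oracle_lacunarity_one(g, m, 4L),
    tolerance = 1e-9
  )
  # masked variant against the same oracle
  m2 <- matrix(runif(256) < 0.8, 16, 16); m2[8, 8] <- TRUE
  expect_equal(
    lacunarity(g, m2, window_sizes = 4L),
    oracle_lacunarity_one(g, m2, 4L),
    tolerance = 1e-9
  )
  expect_error(lacunarity(g, m, window_sizes = 64L), "no window size")
})

test_that("a 20-frame sequence yields 20 single-ROI and 19 pairwise values per feature", {
  p <- fast_sim_params(seed = 3L)
  seq20 <- simulate_sequence(p, breast_id = "x")
  sc <- global_scale(p$t0 - p$delta_t - 0.5, p$t0 + 0.5)
  feats <- extract_frame_features(seq20, sc)
  counts <- dplyr::count(feats, feature)
  pairwise <- c("Battacharyya", "Chi-square", "Intersection", "Spatiogram")
  expect_setequal(counts$feature, thermoseries:::frame_feature_names())
  expect_true(all(counts$n[counts$feature %in% pairwise] == 19L))
  expect_true(all(counts$n[!counts$feature %in% pairwise] == 20L))
})

test_that("a constant sequence gives calibrated pairwise distances", {
  frames <- replicate(4L, matrix(30, 6, 6), simplify = FALSE)
  masks <- replicate(4L, matrix(TRUE, 6, 6), simplify = FALSE)
  s <- thermal_sequence("c", "healthy", frames, masks)
  feats <- extract_frame_features(s, global_scale(25, 35),
                                  frame_feature_config(kmeans_clusters = 2L))
  val <- function(f) feats$value[feats$feature == f]
  expect_equal(val("Battacharyya"), rep(0, 3))
  expect_equal(val("Intersection"), rep(1, 3))
  expect_equal(val("Chi-square"), rep(0, 3))
  expect_equal(val("Spatiogram"), rep(1, 3), tolerance = 1e-9)
  expect_equal(val("Average Temperature"), rep(30, 4))
  expect_equal(val("Lacunarity"), rep(1, 4))
})
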