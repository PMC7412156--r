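#' Mean and standard deviation of ROI temperatures
#'
#' The two simple-statistics features. The standard deviation is the
#' population form (divide by `n`).
#'
#' @param values Numeric vector of in-ROI temperatures (degC).
#' @return Named numeric vector `c(mean =, std =)`.
#' @export
mean_std <- function(values) {
  if (length(values) == 0L) abort("empty ROI")
  m <- mean(values)
  c(mean = m, std = sqrt(mean((values - m)^2)))
}

#' One-dimensional k-means over ROI temperatures
#'
#' Lloyd's algorithm on the scalar temperature values with k-means++
#' seeding. Iteration stops when the change in the total within-group sum
#' of squared residuals (SQRes) falls below `tol`, or after `max_iter`
#' iterations. Clusters that empty keep their previous centroid.
#'
#' @param values Numeric vector (at least `n_clusters` values).
#' @param n_clusters Number of groups (default 9).
#' @param tol Convergence threshold on `|delta SQRes|` (default 0.01).
#' @param max_iter Iteration cap (default 1000).
#' @param seed Optional integer seed for the k-means++ draw.
#' @return List with `centroids` (sorted ascending), `assignments`,
#'   `sqres_per_group`, `sqres_trace` (total SQRes per iteration, attained
#'   after each reassignment), and `iterations`.
#' @export
kmeans1d <- function(values, n_clusters = 9L, tol = 0.01, max_iter = 1000L,
                     seed = NULL) {
  n <- length(values)
  if (n < n_clusters) {
    abort(sprintf("need at least %d values for %d clusters, got %d",
                  n_clusters, n_clusters, n))
  }
  centroids <- with_local_seed(seed, kmeanspp_init(values, n_clusters))
  trace <- numeric(0)
  prev <- Inf
  iter <- 0L
  assign_idx <- rep(1L, n)
  repeat {
    iter <- iter + 1L
    d2 <- outer(values, centroids, function(x, c) (x - c)^2)
    assign_idx <- max.col(-d2, ties.method = "first")
    total <- sum(d2[cbind(seq_len(n), assign_idx)])
    trace <- c(trace, total)
    means <- tapply(values, factor(assign_idx, levels = seq_len(n_clusters)), mean)
    keep <- !is.na(means)
    centroids[keep] <- means[keep]
    if (abs(prev - total) < tol || iter >= max_iter) break
    prev <- total
  }
  ord <- order(centroids)
  rank_of <- match(seq_len(n_clusters), ord)
  sqres <- vapply(seq_len(n_clusters), function(j) {
    sum((values[assign_idx == j] - centroids[[j]])^2)
  }, numeric(1))
  list(
    centroids = centroids[ord],
    assignments = rank_of[assign_idx],
    sqres_per_group = sqres[ord],
    sqres_trace = trace,
    iterations = iter
  )
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre.
kmeanspp_init <- function(values, k) {
  centroids <- numeric(k)
  centroids[[1]] <- values[[sample.int(length(values), 1L)]]
  d2 <- (values - centroids[[1]])^2
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centroids[j:k] <- centroids[[1]]
      break
    }
    pick <- sample.int(length(values), 1L, prob = d2)
    centroids[[j]] <- values[[pick]]
    d2 <- pmin(d2, (values - centroids[[j]])^2)
  }
  centroids
}

#' Grouping feature: hottest k-means centroid
#'
#' Clusters the ROI temperatures of one frame into `n_clusters` groups and
#' returns the largest centroid temperature. Tumor-bearing tissue tends to
#' hold a warm plateau through the cooling recovery, which this centroid
#' tracks robustly.
#'
#' @inheritParams kmeans1d
#' @return The highest centroid temperature (degC).
#' @export
grouping <- function(values, n_clusters = 9L, tol = 0.01, max_iter = 1000L,
                     seed = NULL) {
  max(kmeans1d(values, n_clusters, tol, max_iter, seed)$centroids)
}

#' Gray-level histogram of ROI pixels
#'
#' @param gray_values Integer vector of gray levels in `[0, 255]`.
#' @return Integer vector of 256 counts (bin `i + 1` counts level `i`).
#' @export
gray_histogram <- function(gray_values) {
  if (length(gray_values) == 0L) abort("empty ROI")
  if (any(gray_values < 0 | gray_values > 255)) abort("gray levels must lie in [0, 255]")
  tabulate(gray_values + 1L, nbins = 256L)
}

#' Distance between two histograms
#'
#' Histograms are normalized to probabilities internally. Methods:
#' * `bhattacharyya`: `sqrt(1 - sum(sqrt(p * q)))` — 0 for identical inputs;
#' * `chisquare`: `sum((p - q)^2 / p)` over bins with `p > 0`;
#' * `intersection`: `sum(pmin(p, q))` — 1 for identical inputs.
#'
#' @param h1,h2 Count or probability vectors of equal length.
#' @param method One of `"bhattacharyya"`, `"chisquare"`, `"intersection"`.
#' @return Scalar distance (or similarity, for intersection).
#' @export
hist_distance <- function(h1, h2,
                          method = c("bhattacharyya", "chisquare", "intersection")) {
  method <- match.arg(method)
  if (length(h1) != length(h2)) {
    abort(sprintf("bin mismatch: %d vs %d", length(h1), length(h2)))
  }
  p <- h1 / sum(h1)
  q <- h2 / sum(h2)
  switch(method,
    bhattacharyya = sqrt(max(0, 1 - sum(sqrt(p * q)))),
    chisquare = {
      nz <- p > 0
      sum((p[nz] - q[nz])^2 / p[nz])
    },
    intersection = sum(pmin(p, q))
  )
}

#' Unser sum and difference histograms
#'
#' For each pixel pair displaced by `(dx, dy)` — `dx` columns to the right,
#' `dy` rows down — with both members inside the ROI, the pair's gray-level
#' sum `s = g1 + g2` (range 0..510) and difference `d = g1 - g2`
#' (range -255..255) are accumulated into 511-bin histograms. The two
#' standard neighborhoods are horizontal `(1, 0)` and vertical `(0, 1)`.
#'
#' @param gray Integer gray-image matrix (levels 0..255).
#' @param mask Logical ROI mask of the same dimensions.
#' @param dx,dy Displacement; one of `(1, 0)` or `(0, 1)`.
#' @return A `sum_diff_hist` object: list with `sum_counts` (s = 0..510),
#'   `diff_counts` (d = -255..255), `dx`, `dy`, `n_pairs`.
#' @export
sum_diff_histograms <- function(gray, mask, dx, dy) {
  if (!identical(dim(gray), dim(mask))) abort("gray/mask dimension mismatch")
  if (!(dx == 1 && dy == 0) && !(dx == 0 && dy == 1)) {
    abort("(dx, dy) must be (1, 0) or (0, 1)")
  }
  h <- nrow(gray); w <- ncol(gray)
  if (dx == 1) {
    g1 <- gray[, seq_len(w - 1L), drop = FALSE]
    g2 <- gray[, seq_len(w - 1L) + 1L, drop = FALSE]
    ok <- mask[, seq_len(w - 1L), drop = FALSE] & mask[, seq_len(w - 1L) + 1L, drop = FALSE]
  } else {
    g1 <- gray[seq_len(h - 1L), , drop = FALSE]
    g2 <- gray[seq_len(h - 1L) + 1L, , drop = FALSE]
    ok <- mask[seq_len(h - 1L), , drop = FALSE] & mask[seq_len(h - 1L) + 1L, , drop = FALSE]
  }
  if (!any(ok)) abort("degenerate ROI: no pixel pair with both members inside")
  s <- g1[ok] + g2[ok]
  d <- g1[ok] - g2[ok]
  structure(
    list(
      sum_counts = tabulate(s + 1L, nbins = 511L),
      diff_counts = tabulate(d + 256L, nbins = 511L),
      dx = dx, dy = dy, n_pairs = sum(ok)
    ),
    class = "sum_diff_hist"
  )
}

#' Unser texture estimators from sum/difference histograms
#'
#' The six co-occurrence-style texture features estimated from normalized
#' sum (`Ps`, over `i` = 0..510) and difference (`Pd`, over `j` = -255..255)
#' histograms, with `mu = sum(i * Ps)`:
#' energy `= sum(Ps^2) * sum(Pd^2)`; entropy `= -sum(Ps log Ps) - sum(Pd log
#' Pd)` (natural log, empty bins skipped); contrast `= sum(j^2 Pd)`;
#' variance `= (sum((i - mu)^2 Ps) + sum(j^2 Pd)) / 2`; correlation
#' `= (sum((i - mu)^2 Ps) - sum(j^2 Pd)) / 2`; homogeneity
#' `= sum(Pd / (1 + j^2))`.
#'
#' @param sd A `sum_diff_hist`.
#' @return Named numeric vector of the six features.
#' @export
unser_features <- function(sd) {
  if (!inherits(sd, "sum_diff_hist")) abort("`sd` must be a sum_diff_hist")
  ps <- sd$sum_counts / sum(sd$sum_counts)
  pd <- sd$diff_counts / sum(sd$diff_counts)
  i <- 0:510
  j <- -255:255
  mu <- sum(i * ps)
  vs <- sum((i - mu)^2 * ps)  # spread of the sum histogram
  vd <- sum(j^2 * pd)         # second moment of the difference histogram
  ent <- function(p) {
    nz <- p > 0
    -sum(p[nz] * log(p[nz]))
  }
  c(
    energy = sum(ps^2) * sum(pd^2),
    entropy = ent(ps) + ent(pd),
    contrast = vd,
    variance = (vs + vd) / 2,
    correlation = (vs - vd) / 2,
    homogeneity = sum(pd / (1 + j^2))
  )
}

#' Ecological diversity indices over sum/difference "species"
#'
#' The 511 bins of each histogram are segmented into consecutive,
#' non-overlapping groups of `bin_group` bins (7 divides 511 exactly into
#' 73 groups); each group is a species whose abundance is the summed bin
#' count, giving 73 + 73 = 146 species over the sum and difference
#' histograms together. With abundances `n_i` and `N = sum(n_i)`:
#' Simpson (dominance form) `= sum((n_i / N)^2)`; Berger-Parker
#' `= max(n_i) / N`; McIntosh `= (N - U) / (N - sqrt(N))` with
#' `U = sqrt(sum(n_i^2))`.
#'
#' @param sd A `sum_diff_hist`.
#' @param bin_group Bins per species (default 7; must divide 511).
#' @return Named numeric vector `c(mcintosh =, simpson =, berger_parker =)`.
#' @export
diversity_indices <- function(sd, bin_group = 7L) {
  if (!inherits(sd, "sum_diff_hist")) abort("`sd` must be a sum_diff_hist")
  n <- species_abundances(sd, bin_group)
  N <- sum(n)
  if (N == 0) abort("no pairs: diversity undefined")
  U <- sqrt(sum(n^2))
  mcintosh <- if (N > 1) (N - U) / (N - sqrt(N)) else 0
  c(
    mcintosh = mcintosh,
    simpson = sum((n / N)^2),
    berger_parker = max(n) / N
  )
}

# Abundance vector of the 2 * (511 / bin_group) species.
species_abundances <- function(sd, bin_group = 7L) {
  if (511L %% bin_group != 0L) {
    abort(sprintf("bin_group (%d) must divide 511", bin_group))
  }
  grp <- rep(seq_len(511L %/% bin_group), each = bin_group)
  c(
    as.numeric(rowsum(sd$sum_counts, grp)),
    as.numeric(rowsum(sd$diff_counts, grp))
  )
}

#' Spatiogram of a gray-scale ROI
#'
#' A histogram augmented, per gray-level bin, with the mean and (population)
#' covariance of the spatial positions of the pixels falling in that bin.
#' Positions are 0-based `(row, col)`, origin top-left.
#'
#' @param gray_values Integer vector of in-ROI gray levels (0..255).
#' @param positions Two-column matrix of the pixels' `(row, col)` positions.
#' @return A `spatiogram`: list with `counts` (256), `mu` (256 x 2) and
#'   `sigma` (256 x 2 x 2 array); entries for empty bins are zero.
#' @export
spatiogram <- function(gray_values, positions) {
  if (length(gray_values) == 0L) abort("empty ROI")
  if (length(gray_values) != nrow(positions)) abort("values/positions length mismatch")
  counts <- tabulate(gray_values + 1L, nbins = 256L)
  r <- positions[, 1]; cc <- positions[, 2]
  sums <- rowsum(cbind(r, cc, r * r, cc * cc, r * cc), group = gray_values)
  occ <- as.integer(rownames(sums)) + 1L  # bin index of each occupied row
  n <- counts[occ]
  mu <- matrix(0, 256L, 2L)
  sigma <- array(0, dim = c(256L, 2L, 2L))
  mu[occ, 1] <- sums[, 1] / n
  mu[occ, 2] <- sums[, 2] / n
  sigma[occ, 1, 1] <- sums[, 3] / n - mu[occ, 1]^2
  sigma[occ, 2, 2] <- sums[, 4] / n - mu[occ, 2]^2
  sigma[occ, 1, 2] <- sums[, 5] / n - mu[occ, 1] * mu[occ, 2]
  sigma[occ, 2, 1] <- sigma[occ, 1, 2]
  structure(list(counts = counts, mu = mu, sigma = sigma), class = "spatiogram")
}

#' Similarity between two spatiograms
#'
#' Second-order spatiogram similarity: `rho = sum_b psi_b * sqrt(p_b q_b)`
#' over bins occupied in both inputs, where `p`, `q` are the normalized bin
#' counts and `psi_b` is the normalized Gaussian similarity of the bins'
#' spatial moments, `psi = 8 pi |S1 S2|^(1/4) N(mu1; mu2, 2 (S1 + S2))`.
#' The normalization makes identical spatiograms score exactly 1; any
#' spatial displacement of one input strictly lowers the score. Bin
#' covariances are regularized by `eps * I` so that singleton or collinear
#' bins have proper densities.
#'
#' @param s1,s2 `spatiogram` objects over the same 256-level binning.
#' @param eps Diagonal covariance regularizer in squared pixels
#'   (default 0.25).
#' @return Similarity in `[0, 1]`.
#' @export
spatiogram_similarity <- function(s1, s2, eps = 0.25) {
  if (!inherits(s1, "spatiogram") || !inherits(s2, "spatiogram")) {
    abort("inputs must be spatiograms")
  }
  p <- s1$counts / sum(s1$counts)
  q <- s2$counts / sum(s2$counts)
  both <- which(p > 0 & q > 0)
  if (length(both) == 0L) return(0)
  rho <- 0
  for (b in both) {
    a <- s1$sigma[b, , ] + diag(eps, 2L)
    bb <- s2$sigma[b, , ] + diag(eps, 2L)
    s <- 2 * (a + bb)
    det_s <- s[1, 1] * s[2, 2] - s[1, 2] * s[2, 1]
    m <- s1$mu[b, ] - s2$mu[b, ]
    # quadratic form m' solve(s) m via the 2x2 adjugate
    qf <- (m[1]^2 * s[2, 2] - 2 * m[1] * m[2] * s[1, 2] + m[2]^2 * s[1, 1]) / det_s
    dens <- exp(-0.5 * qf) / (2 * pi * sqrt(det_s))
    det_a <- a[1, 1] * a[2, 2] - a[1, 2]^2
    det_b <- bb[1, 1] * bb[2, 2] - bb[1, 2]^2
    psi <- 8 * pi * (det_a * det_b)^0.25 * dens
    rho <- rho + psi * sqrt(p[[b]] * q[[b]])
  }
  min(max(rho, 0), 1)
}

#' Gliding-box gray-scale lacunarity
#'
#' For each window size `r`, boxes of `r x r` pixels glide with stride 1
#' over the bounding box of the ROI; the mass `M` of a box is the sum of
#' gray values inside it (out-of-ROI pixels contribute zero). The
#' lacunarity at scale `r` is `Lambda(r) = N_B * sum(M^2) / (sum(M))^2`
#' over the `N_B` box positions — the normalized second moment of the mass
#' distribution, 1 for homogeneous mass and larger for gappier textures.
#' The returned feature is the arithmetic mean of `Lambda(r)` over the
#' sizes that admit at least one box inside the bounding box.
#'
#' @param gray Integer gray-image matrix.
#' @param mask Logical ROI mask of the same dimensions.
#' @param window_sizes Box edge lengths in pixels.
#' @param per_size If `TRUE`, return the named vector of `Lambda(r)` values
#'   instead of their mean.
#' @return Scalar lacunarity feature (or per-size vector).
#' @export
lacunarity <- function(gray, mask, window_sizes = c(2L, 4L, 8L, 16L, 32L, 64L),
                       per_size = FALSE) {
  if (!identical(dim(gray), dim(mask))) abort("gray/mask dimension mismatch")
  if (!any(mask)) abort("empty ROI")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  crop <- gray[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  crop[!mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]] <- 0L
  h <- nrow(crop); w <- ncol(crop)
  # integral image with zero padding row/col
  cs <- matrix(apply(crop, 2L, cumsum), h, w)
  P <- matrix(0, h + 1L, w + 1L)
  P[-1L, -1L] <- matrix(t(apply(cs, 1L, cumsum)), h, w)
  lam <- vapply(window_sizes, function(r) {
    if (r > h || r > w) return(NA_real_)
    i <- seq_len(h - r + 1L)
    j <- seq_len(w - r + 1L)
    M <- P[i + r, j + r, drop = FALSE] - P[i, j + r, drop = FALSE] -
      P[i + r, j, drop = FALSE] + P[i, j, drop = FALSE]
    tot <- sum(M)
    if (tot == 0) return(NA_real_)
    length(M) * sum(M^2) / tot^2
  }, numeric(1))
  names(lam) <- as.character(window_sizes)
  valid <- !is.na(lam)
  if (!any(valid)) abort("no window size admits a valid box inside the ROI bounding box")
  if (per_size) lam[valid] else mean(lam[valid])
}

# Canonical phase-1 feature names, in reporting order.
frame_feature_names <- function() {
  unser <- c("Energy", "Entropy", "Contrast", "Variance", "Correlation", "Homogeneity")
  div <- c("Macintosh", "Simpson", "Berger-Parker")
  c(
    "Average Temperature", "Standard Deviation", "Grouping",
    "Battacharyya", "Chi-square", "Intersection",
    paste("Horizontal", unser), paste("Vertical", unser),
    paste("Horizontal", div), paste("Vertical", div),
    "Spatiogram", "Lacunarity"
  )
}

#' Configuration for phase-1 feature extraction
#'
#' @param kmeans_clusters Number of k-means groups for the Grouping feature.
#' @param kmeans_tol Convergence threshold on total SQRes change.
#' @param kmeans_max_iter Iteration cap.
#' @param kmeans_seed Base seed for the k-means++ draws (per-frame seeds are
#'   derived from it); `NULL` leaves the RNG stream alone.
#' @param lacunarity_windows Gliding-box edge lengths.
#' @param species_bin_group Bins per diversity species (must divide 511).
#' @return A named list of settings.
#' @export
frame_feature_config <- function(kmeans_clusters = 9L, kmeans_tol = 0.01,
                                 kmeans_max_iter = 1000L, kmeans_seed = 1L,
                                 lacunarity_windows = c(2L, 4L, 8L, 16L, 32L, 64L),
                                 species_bin_group = 7L) {
  list(
    kmeans_clusters = as.integer(kmeans_clusters),
    kmeans_tol = kmeans_tol,
    kmeans_max_iter = as.integer(kmeans_max_iter),
    kmeans_seed = kmeans_seed,
    lacunarity_windows = as.integer(lacunarity_windows),
    species_bin_group = as.integer(species_bin_group)
  )
}

#' Extract all phase-1 feature series from one thermal sequence
#'
#' Single-ROI features (statistics, Grouping, Unser textures, diversity
#' indices, Lacunarity) yield one value per frame; pairwise features
#' (histogram distances, Spatiogram similarity) yield one value per
#' consecutive frame pair. For the nominal 20-frame exam that is 20 and 19
#' values respectively.
#'
#' @param seq A `thermal_sequence`.
#' @param scale A `global_scale` shared by the whole study.
#' @param config Settings from [frame_feature_config()].
#' @return A tibble with columns `breast_id`, `label`, `feature`, `step`
#'   (0-based frame index, or pair index for pairwise features) and `value`.
#' @export
extract_frame_features <- function(seq, scale, config = frame_feature_config()) {
  n <- length(seq$frames)
  per_frame <- vector("list", n)
  hists <- vector("list", n)
  spats <- vector("list", n)
  for (i in seq_len(n)) {
    frame <- seq$frames[[i]]
    mask <- seq$masks[[i]]
    roi_t <- extract_roi(frame, mask)
    gray <- to_gray(frame, scale)
    roi_g <- extract_roi(gray, mask)
    ms <- mean_std(roi_t$values)
    km_seed <- if (is.null(config$kmeans_seed)) NULL else config$kmeans_seed + i - 1L
    grp <- grouping(roi_t$values, config$kmeans_clusters, config$kmeans_tol,
                    config$kmeans_max_iter, seed = km_seed)
    sd_h <- sum_diff_histograms(gray, mask, 1L, 0L)
    sd_v <- sum_diff_histograms(gray, mask, 0L, 1L)
    uh <- unser_features(sd_h)
    uv <- unser_features(sd_v)
    dh <- diversity_indices(sd_h, config$species_bin_group)
    dv <- diversity_indices(sd_v, config$species_bin_group)
    lac <- lacunarity(gray, mask, config$lacunarity_windows)
    hists[[i]] <- gray_histogram(roi_g$values)
    spats[[i]] <- spatiogram(roi_g$values, roi_g$positions)
    vals <- c(
      ms[["mean"]], ms[["std"]], grp,
      uh, uv,
      dh[["mcintosh"]], dh[["simpson"]], dh[["berger_parker"]],
      dv[["mcintosh"]], dv[["simpson"]], dv[["berger_parker"]],
      lac
    )
    unser_names <- c("Energy", "Entropy", "Contrast", "Variance", "Correlation", "Homogeneity")
    names(vals) <- c(
      "Average Temperature", "Standard Deviation", "Grouping",
      paste("Horizontal", unser_names), paste("Vertical", unser_names),
      paste("Horizontal", c("Macintosh", "Simpson", "Berger-Parker")),
      paste("Vertical", c("Macintosh", "Simpson", "Berger-Parker")),
      "Lacunarity"
    )
    per_frame[[i]] <- tibble::tibble(
      feature = names(vals), step = i - 1L, value = unname(vals)
    )
  }
  pairwise <- purrr::map_dfr(seq_len(n - 1L), function(i) {
    tibble::tibble(
      feature = c("Battacharyya", "Chi-square", "Intersection", "Spatiogram"),
      step = i - 1L,
      value = c(
        hist_distance(hists[[i]], hists[[i + 1L]], "bhattacharyya"),
        hist_distance(hists[[i]], hists[[i + 1L]], "chisquare"),
        hist_distance(hists[[i]], hists[[i + 1L]], "intersection"),
        spatiogram_similarity(spats[[i]], spats[[i + 1L]])
      )
    )
  })
  dplyr::bind_rows(per_frame, pairwise) |>
    dplyr::mutate(
      breast_id = seq$breast_id, label = seq$label, .before = 1L
    ) |>
    dplyr::mutate(feature = factor(.data$feature, levels = frame_feature_names())) |>
    dplyr::arrange(.data$feature, .data$step) |>
    dplyr::mutate(feature = as.character(.data$feature))
}

#' Extract phase-1 feature series for every breast in a cohort
#'
#' @param cohort A `thermal_cohort`.
#' @param scale A `global_scale`; computed from the cohort when `NULL`.
#' @param config Settings from [frame_feature_config()]. Per-breast k-means
#'   seeds are derived from `config$kmeans_seed` so extraction is
#'   reproducible and order-independent.
#' @return Row-bound tibble of [extract_frame_features()] results.
#' @export
extract_cohort_features <- function(cohort, scale = NULL,
                                    config = frame_feature_config()) {
  if (is.null(scale)) scale <- global_extrema(cohort)
  purrr::imap_dfr(cohort$sequences, function(s, i) {
    cfg <- config
    if (!is.null(cfg$kmeans_seed)) {
      cfg$kmeans_seed <- (cfg$kmeans_seed + 1013L * i) %% 2147483647L
    }
    extract_frame_features(s, scale, cfg)
  })
}
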