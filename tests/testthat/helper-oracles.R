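# Independent brute-force oracles: plain double loops coded directly from
# the definitions, deliberately unlike the vectorized implementations.

oracle_roi <- function(frame, mask) {
  vals <- c()
  pos <- NULL
  for (i in seq_len(nrow(frame))) {
    for (j in seq_len(ncol(frame))) {
      if (mask[i, j]) {
        vals <- c(vals, frame[i, j])
        pos <- rbind(pos, c(i - 1L, j - 1L))
      }
    }
  }
  list(values = vals, positions = pos)
}

oracle_gray_hist <- function(gray_values) {
  counts <- integer(256)
  for (v in gray_values) counts[v + 1L] <- counts[v + 1L] + 1L
  counts
}

oracle_sum_diff <- function(gray, mask, dx, dy) {
  sum_counts <- integer(511)
  diff_counts <- integer(511)
  for (i in seq_len(nrow(gray))) {
    for (j in seq_len(ncol(gray))) {
      i2 <- i + dy; j2 <- j + dx
      if (i2 > nrow(gray) || j2 > ncol(gray)) next
      if (!mask[i, j] || !mask[i2, j2]) next
      s <- gray[i, j] + gray[i2, j2]
      d <- gray[i, j] - gray[i2, j2]
      sum_counts[s + 1L] <- sum_counts[s + 1L] + 1L
      diff_counts[d + 256L] <- diff_counts[d + 256L] + 1L
    }
  }
  list(sum_counts = sum_counts, diff_counts = diff_counts)
}

oracle_unser <- function(sum_counts, diff_counts) {
  ps <- sum_counts / sum(sum_counts)
  pd <- diff_counts / sum(diff_counts)
  mu <- 0
  for (i in 0:510) mu <- mu + i * ps[i + 1L]
  energy_s <- 0; energy_d <- 0; ent <- 0; contrast <- 0; vs <- 0; homog <- 0
  for (i in 0:510) {
    p <- ps[i + 1L]
    energy_s <- energy_s + p^2
    if (p > 0) ent <- ent - p * log(p)
    vs <- vs + (i - mu)^2 * p
  }
  for (j in -255:255) {
    p <- pd[j + 256L]
    energy_d <- energy_d + p^2
    if (p > 0) ent <- ent - p * log(p)
    contrast <- contrast + j^2 * p
    homog <- homog + p / (1 + j^2)
  }
  c(energy = energy_s * energy_d, entropy = ent, contrast = contrast,
    variance = (vs + contrast) / 2, correlation = (vs - contrast) / 2,
    homogeneity = homog)
}

oracle_lacunarity_one <- function(gray, mask, r) {
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  crop <- gray[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  crop[!mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]] <- 0L
  masses <- c()
  for (i in seq_len(nrow(crop) - r + 1L)) {
    for (j in seq_len(ncol(crop) - r + 1L)) {
      masses <- c(masses, sum(crop[i:(i + r - 1L), j:(j + r - 1L)]))
    }
  }
  length(masses) * sum(masses^2) / sum(masses)^2
}

oracle_cfs_merit <- function(subset, df, y01) {
  corr <- function(a, b) {
    if (length(unique(a)) == 1L || length(unique(b)) == 1L) return(0)
    abs(sum((a - mean(a)) * (b - mean(b))) /
          sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
  }
  s <- length(subset)
  rcf <- 0
  for (f in subset) rcf <- rcf + corr(df[[f]], y01)
  rcf <- rcf / s
  rff <- 0
  npair <- 0
  if (s > 1) {
    for (a in seq_len(s - 1)) {
      for (b in (a + 1):s) {
        rff <- rff + corr(df[[subset[a]]], df[[subset[b]]])
        npair <- npair + 1
      }
    }
    rff <- rff / npair
  }
  s * rcf / sqrt(s + s * (s - 1) * rff)
}
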