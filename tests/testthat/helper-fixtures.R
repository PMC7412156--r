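# Small in-code fixtures shared across test files.

# Random gray image + blobby mask covering most of it.
random_gray_roi <- function(h = 16L, w = 16L, seed = 1L, mask_frac = 0.8) {
  set.seed(seed)
  gray <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
  mask <- matrix(runif(h * w) < mask_frac, h, w)
  mask[sample(h * w, 1L)] <- TRUE  # never empty
  list(gray = gray, mask = mask)
}

# A tiny in-memory cohort of constant-free frames for IO/scale tests.
tiny_cohort <- function(n_breasts = 2L, n_frames = 3L, h = 4L, w = 5L,
                        seed = 42L) {
  set.seed(seed)
  seqs <- lapply(seq_len(n_breasts), function(b) {
    frames <- lapply(seq_len(n_frames), function(i) {
      f <- matrix(round(runif(h * w, 28, 36), 3L), h, w)
      attr(f, "frame_index") <- i - 1L
      f
    })
    mask <- matrix(TRUE, h, w)
    mask[1, 1] <- FALSE
    thermal_sequence(
      sprintf("B%02d", b), if (b %% 2 == 0) "sick" else "healthy",
      frames, replicate(n_frames, mask, simplify = FALSE)
    )
  })
  thermal_cohort(seqs)
}

# Fast small-image simulation parameters for end-to-end tests.
fast_sim_params <- function(...) {
  args <- list(width = 64L, height = 48L, tumor_radius = 6L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}
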