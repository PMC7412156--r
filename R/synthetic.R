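#' Parameters of the synthetic DIT exam generator
#'
#' The generator emulates the physiology a DIT screening exam exploits:
#' after an induced cooling of the skin, healthy tissue re-warms toward its
#' baseline with an exponential recovery, while a tumor-bearing region is
#' both warmer at baseline and barely affected by the cooling. Per frame
#' `t` (0-based), the temperature at pixel `(x, y)` is
#' `T = T0 + delta * [in tumor] - dT_eff * exp(-t * dt / tau) + noise`,
#' where `dT_eff` equals the cooling drop `delta_T` outside the tumor and
#' `delta_T * (1 - rho)` inside it (`rho = 1`: tumor unaffected by
#' cooling). The ROI mask is a half-ellipse (the breast silhouette) and is
#' identical across frames, so sequences are registered by construction.
#'
#' @param frames Frames per exam (default 20).
#' @param frame_interval_s Seconds between frames (default 15, i.e. about
#'   0.066 images/s over a 5-minute exam).
#' @param width,height Frame size in pixels (default 160 x 120; the
#'   clinical format is 640 x 480 and is available by configuration).
#' @param t0 Baseline skin temperature (degC).
#' @param delta_t Cooling drop at frame 0 (degC).
#' @param tau_s Recovery time constant (s).
#' @param tumor_present Does this breast carry a tumor?
#' @param tumor_center `(row, col)` of the tumor disk; `NULL` centres it in
#'   the upper half of the ROI.
#' @param tumor_radius Disk radius in pixels.
#' @param tumor_delta Baseline elevation inside the tumor (degC).
#' @param tumor_rho Recovery suppression in `[0, 1]` inside the tumor.
#' @param noise_sd Gaussian camera noise (degC); the emulated camera's
#'   thermal sensitivity is below 0.04 degC, hence the 0.03 default.
#' @param seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(frames = 20L, frame_interval_s = 15, width = 160L,
                       height = 120L, t0 = 33, delta_t = 3, tau_s = 180,
                       tumor_present = FALSE, tumor_center = NULL,
                       tumor_radius = 12L, tumor_delta = 1.5, tumor_rho = 0.9,
                       noise_sd = 0.03, seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (tumor_rho < 0 || tumor_rho > 1) abort("tumor_rho must lie in [0, 1]")
  if (tumor_present && tumor_radius <= 0) abort("tumor_radius must be positive")
  structure(
    list(
      frames = as.integer(frames), frame_interval_s = frame_interval_s,
      width = as.integer(width), height = as.integer(height),
      t0 = t0, delta_t = delta_t, tau_s = tau_s,
      tumor_present = tumor_present, tumor_center = tumor_center,
      tumor_radius = tumor_radius, tumor_delta = tumor_delta,
      tumor_rho = tumor_rho, noise_sd = noise_sd, seed = seed
    ),
    class = "sim_params"
  )
}

# Half-ellipse breast mask: full width at the top row, tapering to the
# nipple line; axes chosen to fill ~80% of the frame.
breast_mask <- function(height, width) {
  a <- 0.45 * width   # horizontal semi-axis
  b <- 0.85 * height  # vertical semi-axis (half-ellipse hangs from the top)
  ctr <- (width + 1) / 2
  r <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((cc - ctr) / a)^2 + ((r - 1) / b)^2 <= 1
}

#' Simulate one breast's DIT sequence
#'
#' @param params A [sim_params()] list; its `seed` drives the noise draw.
#' @param breast_id,label Identity of the simulated breast; the label
#'   defaults to `"sick"` when a tumor is present.
#' @return A `thermal_sequence`.
#' @export
simulate_sequence <- function(params = sim_params(), breast_id = "sim",
                              label = NULL) {
  p <- params
  mask <- breast_mask(p$height, p$width)
  if (is.null(label)) label <- if (p$tumor_present) "sick" else "healthy"
  tumor <- matrix(FALSE, p$height, p$width)
  if (p$tumor_present) {
    ctr <- p$tumor_center
    if (is.null(ctr)) ctr <- c(round(0.35 * p$height), round(0.40 * p$width))
    r <- matrix(seq_len(p$height), p$height, p$width)
    cc <- matrix(seq_len(p$width), p$height, p$width, byrow = TRUE)
    tumor <- (r - ctr[1])^2 + (cc - ctr[2])^2 <= p$tumor_radius^2
    if (!all(mask[tumor])) abort("tumor disk extends outside the breast mask")
  }
  dt_eff <- matrix(p$delta_t, p$height, p$width)
  dt_eff[tumor] <- p$delta_t * (1 - p$tumor_rho)
  base <- matrix(p$t0, p$height, p$width)
  base[tumor] <- p$t0 + p$tumor_delta
  frames <- with_local_seed(p$seed, {
    lapply(seq_len(p$frames) - 1L, function(t) {
      f <- base - dt_eff * exp(-t * p$frame_interval_s / p$tau_s)
      if (p$noise_sd > 0) {
        f <- f + matrix(stats::rnorm(length(f), sd = p$noise_sd), nrow(f))
      }
      attr(f, "frame_index") <- t
      f
    })
  })
  thermal_sequence(breast_id, label, frames, replicate(p$frames, mask, simplify = FALSE))
}

#' Simulate a screening cohort
#'
#' Healthy breasts carry no tumor; sick breasts carry a tumor disk with the
#' configured elevation and recovery suppression. Per-breast physiology is
#' jittered (baseline `T0` within +/- 0.5 degC, recovery `tau` within
#' +/- 40 s of the template) from an RNG stream derived from `seed` and the
#' breast index, so generation is reproducible.
#'
#' @param n_healthy,n_sick Breasts per class.
#' @param params Template [sim_params()].
#' @param seed Integer master seed.
#' @return A `thermal_cohort` with unique breast ids `H001..`, `S001..`.
#' @export
simulate_cohort <- function(n_healthy = 32L, n_sick = 32L,
                            params = sim_params(), seed = 7L) {
  make <- function(idx, sick) {
    p <- params
    jit <- with_local_seed((seed + 7919L * idx + 2L * sick) %% 2147483647L, {
      stats::runif(2)
    })
    p$t0 <- params$t0 + (jit[[1]] - 0.5)         # +/- 0.5 degC baseline
    p$tau_s <- params$tau_s + 80 * (jit[[2]] - 0.5)  # +/- 40 s recovery
    p$tumor_present <- sick == 1
    p$seed <- (seed + 104729L * idx + sick) %% 2147483647L
    id <- sprintf("%s%03d", if (sick == 1) "S" else "H", idx)
    simulate_sequence(p, breast_id = id)
  }
  seqs <- c(
    lapply(seq_len(n_healthy), make, sick = 0L),
    lapply(seq_len(n_sick), make, sick = 1L)
  )
  thermal_cohort(seqs, provenance = sprintf("synthetic cohort, seed %d", seed))
}
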