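#' Contact pressure as a function of sensor displacement
#'
#' Ground-truth tissue response of the simulator. Below 90% of the
#' occlusion depth the response is purely linear-plus-quadratic,
#' `CP = stiffness_linear * sd + stiffness_quad * sd^2`; beyond the
#' blend point a smooth hyperbolic term is added that diverges as the
#' displacement approaches the occlusion depth, reproducing the three
#' regimes seen in tonometric practice (elastic, power-law, sharply
#' diverging near occlusion). The function is continuous, continuously
#' differentiable at the blend point, strictly increasing, and
#' `CP(0) = 0`.
#'
#' @param config a [simulation_config()] object.
#' @param sd_mm displacement beyond skin contact, mm (vectorised).
#' @return contact pressure in mmHg.
#' @examples
#' cfg <- simulation_config()
#' cp_from_sd(cfg, c(0, 1, 2))
#' @seealso [sd_from_cp()] for the numerical inverse.
#' @export
cp_from_sd <- function(config, sd_mm) {
  validate_sim_config(config)
  if (any(!is.finite(sd_mm)) || any(sd_mm < 0)) {
    stop("sd_mm must be finite and >= 0")
  }
  occl <- config$occlusion_depth_mm
  if (any(sd_mm >= occl)) {
    stop(sprintf("sd_mm >= occlusion depth (%.3f mm): contact pressure diverges",
                 occl))
  }
  a <- config$stiffness_linear
  b <- config$stiffness_quad
  s0 <- 0.9 * occl
  cp <- a * sd_mm + b * sd_mm^2
  over <- sd_mm > s0
  if (any(over)) {
    # divergence scale tied to the overall stiffness so the blend is smooth
    # (value and first derivative both zero at the blend point)
    k_div <- a + b * occl
    g <- (sd_mm[over] - s0)^2 / (occl - sd_mm[over])
    cp[over] <- cp[over] + k_div * g
  }
  cp
}

#' Invert the contact-pressure response
#'
#' Finds the displacement at which [cp_from_sd()] equals `cp_mmHg` by
#' bisection (tolerance 1e-6 mm). Used to place the stepwise protocol's
#' pressure steps on the displacement axis.
#'
#' @param config a [simulation_config()] object.
#' @param cp_mmHg target contact pressure, mmHg (vectorised).
#' @param tol_mm bisection tolerance, mm.
#' @return displacement beyond contact, mm.
#' @export
sd_from_cp <- function(config, cp_mmHg, tol_mm = 1e-6) {
  validate_sim_config(config)
  if (any(!is.finite(cp_mmHg)) || any(cp_mmHg < 0)) {
    stop("cp_mmHg must be finite and >= 0")
  }
  occl <- config$occlusion_depth_mm
  hi0 <- occl - tol_mm
  cp_hi <- cp_from_sd(config, hi0)
  vapply(cp_mmHg, function(target) {
    if (target == 0) return(0)
    if (target > cp_hi) {
      stop(sprintf("contact pressure %.1f mmHg not attainable below occlusion depth",
                   target))
    }
    lo <- 0
    hi <- hi0
    while (hi - lo > tol_mm) {
      mid <- (lo + hi) / 2
      if (cp_from_sd(config, mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Pulse amplitude envelope as a function of sensor displacement
#'
#' Ground-truth amplitude envelope of the simulator: a Gaussian bell
#' `peak_amplitude * exp(-(sd - optimal_depth)^2 / (2 * width^2))` with
#' its unique maximum at the optimal depth. The optimal depth is the
#' ground-truth pulse depth index.
#'
#' @param config a [simulation_config()] object.
#' @param sd_mm displacement beyond skin contact, mm (vectorised).
#' @return pulse amplitude in mmHg.
#' @examples
#' cfg <- simulation_config()
#' amplitude_at_sd(cfg, cfg$optimal_depth_mm)
#' @export
amplitude_at_sd <- function(config, sd_mm) {
  validate_sim_config(config)
  if (any(!is.finite(sd_mm)) || any(sd_mm < 0)) {
    stop("sd_mm must be finite and >= 0")
  }
  config$peak_amplitude_mmHg *
    exp(-(sd_mm - config$optimal_depth_mm)^2 /
          (2 * config$envelope_width_mm^2))
}

#' Unit beat waveform (truncated Fourier series)
#'
#' Builds the periodic unit pulse shape used by the simulator: a
#' truncated Fourier series `sum_k sin(2 pi k phi) / k` (sawtooth-like,
#' sharp systolic upstroke) with `n_harmonics` terms. The waveform is
#' re-anchored so that phase 0 is the intersecting-tangent foot of the
#' continuous shape (the fiducial point pulse-wave analysis uses to mark
#' beat onset on a smooth upstroke) and normalised so the value at the
#' foot is 0 and the systolic peak is 1. The diastolic minimum therefore
#' lies slightly below 0, exactly as the tangent construction implies.
#'
#' @param n_harmonics number of harmonics (>= 1).
#' @return A list with `fun` (vectorised phase -> value), `peak_phase`
#'   (phase of the systolic peak in [0,1)), and `min_value` (waveform
#'   minimum, <= 0).
#' @keywords internal
beat_waveform <- function(n_harmonics = 3) {
  n <- as.integer(n_harmonics)
  stopifnot(n >= 1)
  raw <- function(phi) {
    out <- 0
    for (k in seq_len(n)) out <- out + sin(2 * pi * k * phi) / k
    out
  }
  draw <- function(phi) {
    out <- 0
    for (k in seq_len(n)) out <- out + 2 * pi * cos(2 * pi * k * phi)
    out
  }
  grid <- seq(0, 1, length.out = 4097)[-4097]
  v <- raw(grid)
  i_min <- which.min(v)
  i_up <- which.max(draw(grid))
  refine <- function(f, i, maximum) {
    lo <- grid[max(1, i - 2)]
    hi <- grid[min(length(grid), i + 2)]
    optimize(f, c(lo, hi), maximum = maximum, tol = 1e-12)
  }
  opt_min <- refine(raw, i_min, maximum = FALSE)
  phi_min <- opt_min$minimum
  v_min <- opt_min$objective
  opt_up <- refine(draw, i_up, maximum = TRUE)
  phi_up <- opt_up$maximum
  slope <- opt_up$objective
  # tangent at the max-upslope point intersects the level of the minimum
  phi_on <- phi_up - (raw(phi_up) - v_min) / slope
  v_on <- raw(phi_on)
  v_max <- max(v)
  scale <- v_max - v_on
  fun <- function(phi) (raw((phi + phi_on) %% 1) - v_on) / scale
  g2 <- seq(0, 1, length.out = 4097)[-4097]
  f2 <- fun(g2)
  list(
    fun = fun,
    peak_phase = g2[which.max(f2)],
    min_value = (v_min - v_on) / scale,
    onset_phase_raw = phi_on
  )
}
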