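#' Simulation configuration for synthetic tonometry recordings
#'
#' Bundles every ground-truth parameter of the synthetic tonometry
#' generator. The defaults describe a continuously evolving tonometric
#' measurement of a radial pulse: the sensor advances at 0.09 mm/s
#' normal to the skin, sampling at 200 Hz, and the pulse amplitude
#' envelope peaks at the configured optimal depth beyond skin contact.
#'
#' The contact-pressure response to displacement beyond contact is
#' linear-plus-quadratic, `CP(sd) = stiffness_linear * sd +
#' stiffness_quad * sd^2`, smoothly blended into a diverging term as the
#' displacement approaches `occlusion_depth_mm` (artery occlusion); see
#' [cp_from_sd()].
#'
#' @param duration_s total recording duration, seconds.
#' @param fs_hz sampling rate, Hz.
#' @param velocity_mm_s actuator advance velocity, mm/s.
#' @param contact_time_s time at which the sensor first touches skin, s.
#' @param optimal_depth_mm displacement beyond contact at which the
#'   pulse amplitude envelope peaks (the ground-truth PDI), mm.
#' @param peak_amplitude_mmHg envelope maximum, mmHg.
#' @param envelope_width_mm Gaussian scale of the amplitude envelope, mm.
#' @param heart_rate_bpm heart rate, beats per minute.
#' @param n_harmonics number of Fourier harmonics of the beat waveform.
#' @param stiffness_linear linear stiffness coefficient, mmHg/mm.
#' @param stiffness_quad quadratic stiffness coefficient, mmHg/mm^2.
#' @param occlusion_depth_mm displacement beyond contact at which
#'   contact pressure diverges (artery occlusion), mm.
#' @param wander_amp_mmHg amplitude of the respiration baseline wander.
#' @param wander_freq_hz frequency of the baseline wander, Hz.
#' @param noise_sd_mmHg standard deviation of additive sensor noise.
#' @param seed integer RNG seed; identical config plus seed gives a
#'   bit-identical recording.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- simulation_config(seed = 1)
#' cfg$optimal_depth_mm
#' @export
simulation_config <- function(duration_s = 80,
                              fs_hz = 200,
                              velocity_mm_s = 0.09,
                              contact_time_s = 3,
                              optimal_depth_mm = 3.8,
                              peak_amplitude_mmHg = 25,
                              envelope_width_mm = 1.5,
                              heart_rate_bpm = 75,
                              n_harmonics = 3,
                              stiffness_linear = 5,
                              stiffness_quad = 8,
                              occlusion_depth_mm = 8,
                              wander_amp_mmHg = 3,
                              wander_freq_hz = 0.25,
                              noise_sd_mmHg = 1,
                              seed = 1L) {
  cfg <- list(
    duration_s = as.numeric(duration_s),
    fs_hz = as.numeric(fs_hz),
    velocity_mm_s = as.numeric(velocity_mm_s),
    contact_time_s = as.numeric(contact_time_s),
    optimal_depth_mm = as.numeric(optimal_depth_mm),
    peak_amplitude_mmHg = as.numeric(peak_amplitude_mmHg),
    envelope_width_mm = as.numeric(envelope_width_mm),
    heart_rate_bpm = as.numeric(heart_rate_bpm),
    n_harmonics = as.integer(n_harmonics),
    stiffness_linear = as.numeric(stiffness_linear),
    stiffness_quad = as.numeric(stiffness_quad),
    occlusion_depth_mm = as.numeric(occlusion_depth_mm),
    wander_amp_mmHg = as.numeric(wander_amp_mmHg),
    wander_freq_hz = as.numeric(wander_freq_hz),
    noise_sd_mmHg = as.numeric(noise_sd_mmHg),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nonneg <- c(
    "duration_s", "velocity_mm_s", "contact_time_s", "optimal_depth_mm",
    "peak_amplitude_mmHg", "envelope_width_mm", "heart_rate_bpm",
    "stiffness_linear", "stiffness_quad", "occlusion_depth_mm",
    "wander_amp_mmHg", "wander_freq_hz", "noise_sd_mmHg"
  )
  for (f in nonneg) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("sim_config field '%s' must be finite and >= 0", f))
    }
  }
  if (cfg$fs_hz <= 0) stop("fs_hz must be > 0")
  if (cfg$duration_s <= cfg$contact_time_s) {
    stop("duration_s must exceed contact_time_s")
  }
  if (cfg$optimal_depth_mm >= cfg$occlusion_depth_mm) {
    stop("optimal_depth_mm must be smaller than occlusion_depth_mm")
  }
  if (cfg$stiffness_linear == 0 && cfg$stiffness_quad == 0) {
    stop("at least one stiffness coefficient must be positive")
  }
  if (cfg$n_harmonics < 1) stop("n_harmonics must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic tonometry configuration\n")
  cat(sprintf("  duration %.1f s at %g Hz, actuator %.3f mm/s, contact at %.2f s\n",
              x$duration_s, x$fs_hz, x$velocity_mm_s, x$contact_time_s))
  cat(sprintf("  envelope: peak %.1f mmHg at depth %.2f mm (width %.2f mm)\n",
              x$peak_amplitude_mmHg, x$optimal_depth_mm, x$envelope_width_mm))
  cat(sprintf("  stiffness: %.1f mmHg/mm + %.1f mmHg/mm^2, occlusion at %.1f mm\n",
              x$stiffness_linear, x$stiffness_quad, x$occlusion_depth_mm))
  cat(sprintf("  heart rate %.0f bpm (%d harmonics); wander %.1f mmHg @ %.2f Hz; noise sd %.1f mmHg; seed %d\n",
              x$heart_rate_bpm, x$n_harmonics, x$wander_amp_mmHg,
              x$wander_freq_hz, x$noise_sd_mmHg, x$seed))
  invisible(x)
}
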