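#' Simulate a stepwise contact-pressure tonometry recording
#'
#' Generates the conventional stepped protocol: after a noise-only
#' lead-in of `contact_time_s`, the contact pressure is held at each of
#' the requested steps for `dwell_s` seconds. The displacement at each
#' step is obtained by numerically inverting the contact-pressure
#' response ([sd_from_cp()]), and the beat train at that step is scaled
#' by the amplitude envelope at the inverted displacement. Defaults
#' follow the usual five-step protocol: 40, 70, 110, 140, 180 mmHg for
#' 5 s each.
#'
#' @param config a [simulation_config()] object.
#' @param step_pressures_mmHg strictly increasing step pressures, mmHg.
#' @param dwell_s hold duration per step, seconds.
#' @return A list of class `sim_result` with `recording` (protocol
#'   `"stepwise"`, with `meta$step_pressures_mmHg`, `meta$dwell_s`,
#'   `meta$lead_in_s`) and `truth` (`true_step_sd_mm`,
#'   `true_step_amplitudes_mmHg`, `true_onset_times_s`, `config`).
#' @examples
#' sim <- simulate_stepwise(simulation_config(seed = 3))
#' sim$truth$true_step_amplitudes_mmHg
#' @export
simulate_stepwise <- function(config,
                              step_pressures_mmHg = c(40, 70, 110, 140, 180),
                              dwell_s = 5) {
  validate_sim_config(config)
  if (length(step_pressures_mmHg) < 2 ||
      any(diff(step_pressures_mmHg) <= 0)) {
    stop("step_pressures_mmHg must be strictly increasing")
  }
  fs <- config$fs_hz
  lead_in <- config$contact_time_s
  n_steps <- length(step_pressures_mmHg)
  total_s <- lead_in + n_steps * dwell_s
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs

  step_sd <- sd_from_cp(config, step_pressures_mmHg)  # errors if unattainable
  step_amp <- amplitude_at_sd(config, step_sd)

  set.seed(config$seed)
  noise <- rnorm(n, 0, config$noise_sd_mmHg)
  wander_phase <- runif(1, 0, 2 * pi)

  wf <- beat_waveform(config$n_harmonics)
  period <- 60 / config$heart_rate_bpm

  x <- noise
  post <- t >= lead_in
  step_idx <- pmin(n_steps, pmax(1L, 1 + floor((t - lead_in) / dwell_s)))
  phase <- (t - lead_in) / period
  pulse <- step_amp[step_idx] * wf$fun(phase %% 1)
  # wander amplitude couples with contact pressure (cf. simulate_cetm)
  wander <- config$wander_amp_mmHg *
    pmin(1, step_pressures_mmHg[step_idx] / 20) *
    sin(2 * pi * config$wander_freq_hz * (t - lead_in) + wander_phase)
  x[post] <- x[post] + step_pressures_mmHg[step_idx[post]] +
    wander[post] + pulse[post]

  onsets <- lead_in + period * seq(0, floor((total_s - lead_in) / period))
  onsets <- onsets[onsets < total_s]

  rec <- tonometry_recording(
    x, fs, protocol = "stepwise",
    meta = list(step_pressures_mmHg = step_pressures_mmHg,
                dwell_s = dwell_s, lead_in_s = lead_in)
  )
  truth <- list(
    true_step_sd_mm = step_sd,
    true_step_amplitudes_mmHg = step_amp,
    true_contact_time_s = lead_in,
    true_onset_times_s = onsets,
    config = config
  )
  structure(list(recording = rec, truth = truth), class = "sim_result")
}
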