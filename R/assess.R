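#' Assess pulse depth from a tonometry recording
#'
#' The package's main entry point: runs the full pipeline on one
#' recording -- trend/pulsatile decomposition, intersecting-tangent beat
#' detection, amplitude measurement, skin-contact detection (CETM),
#' amplitude envelope construction -- and computes the three pulse-depth
#' indices: optimal contact pressure (OCP) with its normalised
#' coefficient `CFS_ocp`, the pulse-amplitude-difference coefficient
#' `CFS_pad`, and (CETM only) the sensor-displacement based pulse depth
#' index PDI. Stepwise recordings yield the CP-based indices with PDI
#' `NA` by protocol.
#'
#' @param recording a [tonometry_recording()].
#' @param contact_time_s optional explicit skin-contact time overriding
#'   automatic detection (CETM).
#' @param pairs_mode sector comparison mode for `CFS_pad`; see
#'   [compute_cfs_pad()].
#' @param smooth_window envelope smoothing window in beats.
#' @param filter_low_hz,filter_high_hz band-pass edges for the beat
#'   detection pass.
#' @param trend_cutoff_hz low-pass trend cut-off for the first
#'   decomposition pass.
#' @param cfs_pad_range_mmHg contact-pressure range segmented for
#'   `CFS_pad`.
#' @return An object of class `depth_assessment`: list with
#'   \describe{
#'     \item{indices}{named list `ocp_mmHg`, `cfs_ocp`, `cfs_pad`,
#'       `pdi_mm`, `sd_contact_mm`, `sd_optimal_mm` (+ boundary flags).}
#'     \item{envelope}{the `amplitude_envelope`.}
#'     \item{beats}{the measured `beat_series`.}
#'     \item{decomposed}{the final `decomposed_signal`.}
#'     \item{contact}{contact-detection result (CETM).}
#'     \item{recording}{the input recording.}
#'   }
#' @examples
#' sim <- simulate_cetm(simulation_config(seed = 11))
#' fit <- assess_depth(sim$recording)
#' coef(fit)
#' @export
assess_depth <- function(recording,
                         contact_time_s = NULL,
                         pairs_mode = c("outer", "averaged"),
                         smooth_window = 5,
                         filter_low_hz = 0.5, filter_high_hz = 20,
                         trend_cutoff_hz = 0.3,
                         cfs_pad_range_mmHg = c(60, 195)) {
  stopifnot(inherits(recording, "tonometry_recording"))
  pairs_mode <- match.arg(pairs_mode)
  x <- recording$pressure_mmHg
  fs <- recording$fs_hz

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }

  # pass 1: band-pass pulsatile for provisional beat feet
  puls1 <- stage("preprocess", bandpass_filter(x, fs, filter_low_hz, filter_high_hz))
  beats1 <- stage("beats", detect_onsets(puls1, fs))

  # pass 2: re-anchor the trend on the detected feet
  dec <- stage("preprocess",
               remove_baseline(x, fs,
                               foot_times_s = if (nrow(beats1) >= 4) beats1$onset_time_s else NULL,
                               trend_cutoff_hz = trend_cutoff_hz,
                               noise_cutoff_hz = filter_high_hz))
  beats <- stage("beats", detect_onsets(dec$pulsatile_mmHg, fs))
  beats <- stage("beats", measure_amplitudes(dec$pulsatile_mmHg, beats))

  contact <- NULL
  if (recording$protocol == "cetm") {
    if (!is.null(contact_time_s)) {
      contact <- list(contact_time_s = contact_time_s,
                      sd_contact_mm = recording$velocity_mm_s * contact_time_s)
    } else {
      trend_lp <- stage("preprocess", lowpass_filter(x, fs, trend_cutoff_hz))
      contact <- stage("contact", detect_contact_point(recording, trend_lp))
    }
  }

  envelope <- stage("envelope", build_envelope(recording, dec, beats, contact))

  ocp <- stage("indices", compute_ocp(envelope, smooth_window))
  cfs_ocp <- stage("indices", compute_cfs_ocp(ocp$ocp_mmHg,
                                              attr(envelope, "cp_min_mmHg"),
                                              attr(envelope, "cp_max_mmHg")))
  pad <- stage("indices", compute_cfs_pad(envelope, cfs_pad_range_mmHg,
                                          pairs_mode = pairs_mode))
  if (recording$protocol == "cetm") {
    pdi <- stage("indices", compute_pdi(envelope, contact$sd_contact_mm,
                                        smooth_window))
  } else {
    pdi <- list(pdi_mm = NA_real_, sd_optimal_mm = NA_real_, boundary = FALSE)
  }

  indices <- list(
    ocp_mmHg = ocp$ocp_mmHg,
    cfs_ocp = cfs_ocp,
    cfs_pad = pad$cfs_pad,
    pdi_mm = pdi$pdi_mm,
    sd_contact_mm = if (is.null(contact)) NA_real_ else contact$sd_contact_mm,
    sd_optimal_mm = pdi$sd_optimal_mm,
    ocp_boundary = ocp$boundary,
    pdi_boundary = pdi$boundary,
    h_shallow_mmHg = pad$h_shallow_mmHg,
    h_deep_mmHg = pad$h_deep_mmHg
  )

  structure(
    list(indices = indices, envelope = envelope, beats = beats,
         decomposed = dec, contact = contact, recording = recording),
    class = "depth_assessment"
  )
}

#' @export
print.depth_assessment <- function(x, ...) {
  ind <- x$indices
  cat(sprintf("Pulse depth assessment (%s protocol)\n", x$recording$protocol))
  cat(sprintf("  OCP     %8.2f mmHg%s\n", ind$ocp_mmHg,
              if (isTRUE(ind$ocp_boundary)) " [boundary]" else ""))
  cat(sprintf("  CFS_ocp %8.3f\n", ind$cfs_ocp))
  cat(sprintf("  CFS_pad %8.3f\n", ind$cfs_pad))
  if (is.na(ind$pdi_mm)) {
    cat("  PDI     not applicable (stepwise protocol)\n")
  } else {
    cat(sprintf("  PDI     %8.2f mm%s\n", ind$pdi_mm,
                if (isTRUE(ind$pdi_boundary)) " [boundary]" else ""))
  }
  invisible(x)
}

#' @export
coef.depth_assessment <- function(object, ...) {
  ind <- object$indices
  c(ocp_mmHg = ind$ocp_mmHg, cfs_ocp = ind$cfs_ocp,
    cfs_pad = ind$cfs_pad, pdi_mm = ind$pdi_mm)
}

#' @export
summary.depth_assessment <- function(object, ...) {
  ind <- object$indices
  cat(sprintf("Pulse depth assessment (%s protocol)\n", object$recording$protocol))
  cat(sprintf("  recording: %d samples at %g Hz\n",
              length(object$recording$pressure_mmHg), object$recording$fs_hz))
  cat(sprintf("  beats: %d detected\n", nrow(object$beats)))
  if (!is.null(object$contact)) {
    cat(sprintf("  contact: %.2f s (sd %.3f mm)\n",
                object$contact$contact_time_s, object$contact$sd_contact_mm))
  }
  env <- object$envelope
  cat(sprintf("  envelope: %d points, CP %.1f-%.1f mmHg\n", nrow(env),
              attr(env, "cp_min_mmHg"), attr(env, "cp_max_mmHg")))
  cat(sprintf("  H_shallow %.2f, H_deep %.2f mmHg\n",
              ind$h_shallow_mmHg, ind$h_deep_mmHg))
  print(object)
  invisible(object)
}

#' Plot a pulse depth assessment
#'
#' Two panels: the amplitude envelope over sensor displacement (CETM)
#' with the contact point and the PDI span marked, and the envelope over
#' contact pressure with the OCP marked.
#'
#' @param x a `depth_assessment`.
#' @param ... passed to [plot()].
#' @export
plot.depth_assessment <- function(x, ...) {
  env <- x$envelope
  ind <- x$indices
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  if (x$recording$protocol == "cetm") {
    plot(env$sd_mm, env$amplitude_mmHg, pch = 16, cex = 0.5,
         xlab = "sensor displacement (mm)", ylab = "pulse amplitude (mmHg)",
         main = "amplitude envelope", ...)
    lines(env$sd_mm, smooth_envelope(env$amplitude_mmHg), col = 2, lwd = 2)
    abline(v = c(ind$sd_contact_mm, ind$sd_optimal_mm), lty = 2, col = 4)
    mtext(sprintf("PDI = %.2f mm", ind$pdi_mm), cex = 0.8)
  } else {
    plot(seq_len(nrow(env)), env$amplitude_mmHg, type = "b",
         xlab = "step", ylab = "pulse amplitude (mmHg)",
         main = "step amplitudes", ...)
  }
  plot(env$cp_mmHg, env$amplitude_mmHg, pch = 16, cex = 0.5,
       xlab = "contact pressure (mmHg)", ylab = "pulse amplitude (mmHg)",
       main = "P-H curve", ...)
  abline(v = ind$ocp_mmHg, lty = 2, col = 2)
  mtext(sprintf("OCP = %.1f mmHg", ind$ocp_mmHg), cex = 0.8)
  invisible(x)
}
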