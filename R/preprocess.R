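#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`) so that beat onset timing is not biased by group
#' delay. The input is extended by odd reflection at both ends before
#' filtering to suppress edge transients (tonometric recordings carry a
#' large pressure ramp), and the extension is discarded afterwards, so
#' length is preserved. Defaults of 0.5--20 Hz keep the heart-rate
#' fundamental and roughly its first ten harmonics at rest.
#'
#' @param x numeric signal.
#' @param fs_hz sampling rate, Hz.
#' @param low_hz lower band edge, Hz.
#' @param high_hz upper band edge, Hz.
#' @param order Butterworth order (per edge, before the forward-backward
#'   pass doubles the effective order).
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs_hz, low_hz = 0.5, high_hz = 20, order = 4) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs_hz / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs_hz/2")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  filtfilt_padded(bf, x, n_pad = round(3 * fs_hz / low_hz))
}

#' Zero-phase low-pass filter (internal)
#'
#' @keywords internal
lowpass_filter <- function(x, fs_hz, cutoff_hz, order = 2) {
  if (!(cutoff_hz > 0 && cutoff_hz < fs_hz / 2)) {
    stop("cutoff must satisfy 0 < cutoff_hz < fs_hz/2")
  }
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  filtfilt_padded(bf, x, n_pad = round(3 * fs_hz / cutoff_hz))
}

# forward-backward filtering with odd-reflection padding at both ends;
# odd reflection continues a ramp with its slope, so filtfilt start-up
# transients do not contaminate the trend estimate. The reflection is
# anchored on a short local linear fit rather than the single edge
# sample: anchoring on one noisy sample would inject a DC step of twice
# that sample's noise, which the filter would smear into the signal.
filtfilt_padded <- function(bf, x, n_pad) {
  n <- length(x)
  n_pad <- max(1, min(n - 1, n_pad))
  anchor <- function(idx, at) {
    if (length(idx) < 3) return(x[at])
    tt <- idx - at
    b <- sum((tt - mean(tt)) * x[idx]) / sum((tt - mean(tt))^2)
    mean(x[idx]) - b * mean(tt)
  }
  ka <- max(9, min(n - 1, round(n_pad / 6)))
  a1 <- anchor(seq_len(ka), 1)
  a2 <- anchor((n - ka + 1):n, n)
  pre <- 2 * a1 - rev(x[2:(n_pad + 1)])
  post <- 2 * a2 - rev(x[(n - n_pad):(n - 1)])
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(n_pad + 1):(n_pad + n)]
}

#' Decompose a recording into slow trend and pulsatile component
#'
#' Separates a tonometric pressure signal into a slow trend -- the
#' contact-pressure baseline plus any residual respiration wander -- and
#' a zero-baseline pulsatile component. The signal is first denoised
#' with a zero-phase low-pass at `noise_cutoff_hz`; the trend is then a
#' natural cubic spline through the per-beat foot values when
#' `foot_times_s` is supplied (the usual second pass, re-anchored on
#' detected beat feet), or a zero-phase low-pass at `trend_cutoff_hz`
#' otherwise. `trend + pulsatile` reconstructs the denoised signal
#' exactly.
#'
#' For constant-velocity (CETM) recordings the contact-pressure ramp is
#' deliberately part of the trend: the trend doubles as the per-beat
#' contact-pressure estimate downstream.
#'
#' @param x numeric pressure signal, mmHg.
#' @param fs_hz sampling rate, Hz.
#' @param foot_times_s optional beat foot (onset) times, seconds; with
#'   fewer than 4 feet the spline is not identifiable and the function
#'   falls back to the low-pass trend (flagged in the result).
#' @param trend_cutoff_hz low-pass trend cut-off, Hz.
#' @param noise_cutoff_hz denoising cut-off, Hz.
#' @return An object of class `decomposed_signal`: list with
#'   `trend_mmHg`, `pulsatile_mmHg`, `fs_hz`, `trend_method`
#'   (`"spline"` or `"lowpass"`).
#' @export
remove_baseline <- function(x, fs_hz, foot_times_s = NULL,
                            trend_cutoff_hz = 0.3, noise_cutoff_hz = 20) {
  if (length(x) < 2 * fs_hz) stop("signal must be at least 2 s long")
  denoised <- lowpass_filter(x, fs_hz, noise_cutoff_hz, order = 4)
  method <- "lowpass"
  if (!is.null(foot_times_s) && length(foot_times_s) >= 4) {
    t <- (seq_along(x) - 1) / fs_hz
    idx <- round(foot_times_s * fs_hz) + 1
    idx <- idx[idx >= 1 & idx <= length(x)]
    trend <- spline(t[idx], denoised[idx], xout = t,
                    method = "natural")$y
    # hold the trend flat outside the anchored span instead of
    # extrapolating the end splines into the pre-contact region
    trend[t < t[idx[1]]] <- denoised[idx[1]]
    trend[t > t[idx[length(idx)]]] <- denoised[idx[length(idx)]]
    method <- "spline"
  } else {
    if (!is.null(foot_times_s)) {
      warning("fewer than 4 beat feet: falling back to low-pass trend")
    }
    trend <- lowpass_filter(x, fs_hz, trend_cutoff_hz, order = 2)
  }
  structure(
    list(trend_mmHg = trend,
         pulsatile_mmHg = denoised - trend,
         fs_hz = fs_hz,
         trend_method = method),
    class = "decomposed_signal"
  )
}

#' Spectral inspection utility
#'
#' Returns the one-sided amplitude spectrum of a signal segment --
#' a quality-control helper for checking wander and noise content, not
#' part of the removal path.
#'
#' @param x numeric signal.
#' @param fs_hz sampling rate, Hz.
#' @return data frame with `freq_hz` and `amplitude`.
#' @export
amplitude_spectrum <- function(x, fs_hz) {
  n <- length(x)
  sp <- abs(fft(x - mean(x)))[seq_len(floor(n / 2))] * 2 / n
  data.frame(freq_hz = (seq_len(floor(n / 2)) - 1) * fs_hz / n,
             amplitude = sp)
}
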