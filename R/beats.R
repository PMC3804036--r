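#' Detect beat onsets with the intersecting tangent method
#'
#' Segments a baseline-removed pulsatile signal into beats. Candidate
#' systolic peaks are found by adaptive-threshold peak picking; each
#' onset is then refined geometrically: the tangent at the point of
#' maximum systolic upslope (slope from a 5-sample centred difference)
#' is intersected with the horizontal line through the preceding local
#' minimum. Onsets are never placed later than the upslope point nor
#' earlier than the preceding minimum.
#'
#' Beats implying a non-physiological inter-onset interval (outside
#' `ibi_range_s`, default 0.3--2 s, i.e. 30--200 bpm) are dropped. If no
#' peak clears the threshold an empty series is returned with attribute
#' `flagged = TRUE`.
#'
#' @param pulsatile baseline-removed pulse signal, mmHg.
#' @param fs_hz sampling rate, Hz.
#' @param ibi_range_s plausibility gate on inter-beat intervals, s.
#' @param slope_halfwin_samples half-window of the centred slope
#'   estimator (2 gives the 5-sample, 25 ms at 200 Hz, default).
#' @param rel_threshold fraction of the local amplitude scale a peak
#'   must exceed.
#' @return An object of class `beat_series`: data frame with columns
#'   `onset_time_s`, `onset_index`, `peak_time_s`, `peak_index`,
#'   `foot_value_mmHg`, `peak_value_mmHg`, `amplitude_mmHg`, plus
#'   attributes `fs_hz` and `flagged`. Amplitude columns are `NA` until
#'   [measure_amplitudes()] fills them.
#' @export
detect_onsets <- function(pulsatile, fs_hz, ibi_range_s = c(0.3, 2),
                          slope_halfwin_samples = 2, rel_threshold = 0.35) {
  n <- length(pulsatile)
  if (n < fs_hz) stop("pulsatile signal shorter than 1 s")
  x <- pulsatile

  # noise scale from the quietest 1 s segments: beats raise a segment's
  # spread well above the in-band noise floor, so a low quantile of the
  # per-segment MAD estimates the noise even though noise and pulse
  # share the pass band
  n_seg <- floor(n / fs_hz)
  seg_mad <- vapply(seq_len(max(1, n_seg)), function(i) {
    mad(x[((i - 1) * fs_hz + 1):min(n, i * fs_hz)])
  }, numeric(1))
  sigma <- min(seg_mad)

  # local maxima at least min-IBI apart
  dx <- diff(x)
  cand <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1
  # adaptive threshold: fraction of the rolling 90th percentile of |x|
  # over a +/- 2 s window, with an absolute noise floor
  win <- round(2 * fs_hz)
  thr <- vapply(cand, function(i) {
    lo <- max(1, i - win); hi <- min(n, i + win)
    max(rel_threshold * quantile(abs(x[lo:hi]), 0.9, names = FALSE),
        5 * sigma, 1e-9)
  }, numeric(1))
  cand <- cand[x[cand] > thr]

  # enforce minimum separation, keeping the taller peak
  min_gap <- round(ibi_range_s[1] * fs_hz)
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) && i - peaks[length(peaks)] < min_gap) {
      if (x[i] > x[peaks[length(peaks)]]) peaks[length(peaks)] <- i
    } else {
      peaks <- c(peaks, i)
    }
  }

  if (!length(peaks)) {
    return(empty_beat_series(fs_hz, flagged = TRUE))
  }

  # prominence pass against secondary (dicrotic-like) bumps: two peaks
  # separated by a shallow valley belong to the same beat -- a true
  # systolic peak is preceded by a foot near the baseline
  repeat {
    if (length(peaks) < 2) break
    merged <- FALSE
    for (j in seq_len(length(peaks) - 1)) {
      valley <- min(x[peaks[j]:peaks[j + 1]])
      if (valley > 0.5 * min(x[peaks[j]], x[peaks[j + 1]])) {
        drop <- if (x[peaks[j]] >= x[peaks[j + 1]]) j + 1 else j
        peaks <- peaks[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  hw <- slope_halfwin_samples
  kernel_t <- (-hw:hw) / fs_hz
  onset_t <- numeric(0)
  peak_keep <- integer(0)
  prev_peak <- 1L
  for (p in peaks) {
    lo <- max(prev_peak, p - round(ibi_range_s[2] * fs_hz), 1L)
    seg <- lo:p
    imin <- seg[which.min(x[seg])]
    if (imin >= p) { prev_peak <- p; next }
    rise <- imin:p
    slopes <- vapply(rise, function(i) {
      lo2 <- max(1, i - hw); hi2 <- min(n, i + hw)
      tt <- ((lo2:hi2) - i) / fs_hz
      sum((tt - mean(tt)) * x[lo2:hi2]) / sum((tt - mean(tt))^2)
    }, numeric(1))
    iup <- rise[which.max(slopes)]
    m <- max(slopes)
    if (!is.finite(m) || m <= 0) { prev_peak <- p; next }
    t_up <- (iup - 1) / fs_hz
    t_on <- t_up - (x[iup] - x[imin]) / m
    # never later than the upslope point, never earlier than the minimum
    t_on <- min(max(t_on, (imin - 1) / fs_hz), t_up)
    onset_t <- c(onset_t, t_on)
    peak_keep <- c(peak_keep, p)
    prev_peak <- p
  }

  if (!length(onset_t)) return(empty_beat_series(fs_hz, flagged = TRUE))

  # plausibility gate on inter-onset intervals: drop the later beat of
  # an implausibly short pair
  keep <- rep(TRUE, length(onset_t))
  last_kept <- 1
  for (j in seq_along(onset_t)[-1]) {
    ibi <- onset_t[j] - onset_t[last_kept]
    if (ibi < ibi_range_s[1]) {
      keep[j] <- FALSE
    } else {
      last_kept <- j
    }
  }
  if (any(!keep)) {
    message(sprintf("dropped %d beat(s) with inter-beat interval below the %.2f s plausibility gate",
                    sum(!keep), ibi_range_s[1]))
  }
  onset_t <- onset_t[keep]; peak_keep <- peak_keep[keep]

  beats <- data.frame(
    onset_time_s = onset_t,
    onset_index = as.integer(round(onset_t * fs_hz) + 1L),
    peak_time_s = (peak_keep - 1) / fs_hz,
    peak_index = peak_keep,
    foot_value_mmHg = NA_real_,
    peak_value_mmHg = NA_real_,
    amplitude_mmHg = NA_real_
  )
  structure(beats, class = c("beat_series", "data.frame"),
            fs_hz = fs_hz, flagged = FALSE)
}

empty_beat_series <- function(fs_hz, flagged = FALSE) {
  structure(
    data.frame(onset_time_s = numeric(0), onset_index = integer(0),
               peak_time_s = numeric(0), peak_index = integer(0),
               foot_value_mmHg = numeric(0), peak_value_mmHg = numeric(0),
               amplitude_mmHg = numeric(0)),
    class = c("beat_series", "data.frame"), fs_hz = fs_hz, flagged = flagged
  )
}

#' Measure per-beat pulse amplitudes
#'
#' For each detected beat the foot value is the pulsatile signal at the
#' onset sample, the peak value is the maximum over `[onset, next
#' onset)` (to the end of the signal for the last beat), and the
#' amplitude is their difference (peak-to-foot). Beats with an empty
#' window are dropped.
#'
#' @param pulsatile baseline-removed pulse signal, mmHg.
#' @param series a `beat_series` from [detect_onsets()].
#' @return the `beat_series` with amplitude columns filled.
#' @export
measure_amplitudes <- function(pulsatile, series) {
  stopifnot(inherits(series, "beat_series"))
  fs <- attr(series, "fs_hz")
  n <- length(pulsatile)
  nb <- nrow(series)
  if (!nb) return(series)
  keep <- rep(TRUE, nb)
  # bound each search window by ~1.5 median inter-beat intervals so a
  # missed neighbour (or the end of the recording) cannot hand a beat a
  # window far beyond its own cycle
  med_ibi <- if (nb > 1) median(diff(series$onset_index)) else round(fs)
  max_win <- round(1.5 * med_ibi)
  for (j in seq_len(nb)) {
    i0 <- series$onset_index[j]
    i1 <- if (j < nb) series$onset_index[j + 1] - 1L else n
    i1 <- min(i1, i0 + max_win)
    if (i0 > n || i1 < i0) { keep[j] <- FALSE; next }
    if (j == nb && (i1 - i0) < 0.6 * med_ibi) {
      # incomplete final cycle: its peak may lie beyond the recording
      keep[j] <- FALSE
      next
    }
    series$foot_value_mmHg[j] <- pulsatile[i0]
    w <- i0:min(i1, n)
    ipk <- w[which.max(pulsatile[w])]
    series$peak_value_mmHg[j] <- pulsatile[ipk]
    series$peak_time_s[j] <- (ipk - 1) / fs
    series$peak_index[j] <- ipk
    series$amplitude_mmHg[j] <- series$peak_value_mmHg[j] - series$foot_value_mmHg[j]
  }
  out <- series[keep, , drop = FALSE]
  structure(out, class = c("beat_series", "data.frame"),
            fs_hz = fs, flagged = attr(series, "flagged"))
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series: %d beats at %g Hz%s\n", nrow(x), attr(x, "fs_hz"),
              if (isTRUE(attr(x, "flagged"))) " [flagged]" else ""))
  if (nrow(x)) {
    ibi <- diff(x$onset_time_s)
    cat(sprintf("  median inter-beat interval %.3f s (%.1f bpm)\n",
                median(ibi), 60 / median(ibi)))
    if (!all(is.na(x$amplitude_mmHg))) {
      cat(sprintf("  amplitudes %.2f-%.2f mmHg\n",
                  min(x$amplitude_mmHg, na.rm = TRUE),
                  max(x$amplitude_mmHg, na.rm = TRUE)))
    }
  }
  invisible(x)
}
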