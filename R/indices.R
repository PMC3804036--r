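#' Smooth a beat-by-beat amplitude sequence
#'
#' Moving median then moving average (default window 5 beats); a single
#' aberrant beat must not decide the envelope maximum. Used by both
#' [compute_ocp()] and [compute_pdi()] for CETM envelopes.
#'
#' @param amplitude numeric amplitude sequence.
#' @param window odd window length in beats.
#' @return smoothed sequence, same length.
#' @keywords internal
smooth_envelope <- function(amplitude, window = 5) {
  n <- length(amplitude)
  if (n < window) return(amplitude)
  med <- stats::runmed(amplitude, window, endrule = "keep")
  hw <- (window - 1) / 2
  out <- vapply(seq_len(n), function(i) {
    mean(med[max(1, i - hw):min(n, i + hw)])
  }, numeric(1))
  out
}

#' Optimal contact pressure (OCP)
#'
#' Contact pressure at which the pulse amplitude envelope peaks. For
#' stepwise envelopes a cubic interpolant through the `(CP, H)` points
#' is maximised over the applied-CP range (five points are too sparse to
#' locate the peak directly); for CETM envelopes the beat-by-beat
#' amplitude sequence is smoothed ([smooth_envelope()]) and the contact
#' pressure at its argmax is read off. Ties break toward the smallest
#' CP; a maximum on the boundary of the CP range is returned with
#' `boundary = TRUE` (truncated envelope).
#'
#' @param envelope an `amplitude_envelope` from [build_envelope()].
#' @param smooth_window smoothing window in beats (CETM).
#' @return list with `ocp_mmHg`, `boundary`, and for CETM envelopes
#'   `argmax_index` (beat index of the smoothed argmax).
#' @export
compute_ocp <- function(envelope, smooth_window = 5) {
  stopifnot(inherits(envelope, "amplitude_envelope"))
  protocol <- attr(envelope, "protocol")
  cp_min <- attr(envelope, "cp_min_mmHg")
  cp_max <- attr(envelope, "cp_max_mmHg")

  if (protocol == "stepwise") {
    if (nrow(envelope) < 3) stop("need at least 3 envelope points")
    f <- splinefun(envelope$cp_mmHg, envelope$amplitude_mmHg, method = "natural")
    grid <- seq(cp_min, cp_max, length.out = 2001)
    vals <- f(grid)
    i <- which(vals >= max(vals) - 1e-12)[1]  # ties: smallest CP
    ocp <- grid[i]
    boundary <- i == 1 || i == length(grid)
    return(list(ocp_mmHg = ocp, boundary = boundary))
  }

  if (nrow(envelope) < 5) stop("need at least 5 beats for a CETM envelope")
  sm <- smooth_envelope(envelope$amplitude_mmHg, smooth_window)
  i <- which(sm >= max(sm) - 1e-12)[1]
  list(ocp_mmHg = envelope$cp_mmHg[i],
       boundary = i == 1 || i == nrow(envelope),
       argmax_index = i)
}

#' Normalised OCP coefficient
#'
#' `CFS_ocp = (OCP - CP_min) / (CP_max - CP_min)`: the optimal contact
#' pressure normalised by the range of applied contact pressure. Bounded
#' in \\[0, 1\\]; values near 0 indicate a shallow (floating-like) pulse,
#' values near 1 a deep (sunken-like) pulse.
#'
#' @param ocp_mmHg optimal contact pressure, mmHg.
#' @param cp_min_mmHg minimum applied contact pressure, mmHg.
#' @param cp_max_mmHg maximum applied contact pressure, mmHg.
#' @return `cfs_ocp` in \\[0, 1\\].
#' @examples
#' compute_cfs_ocp(110, 40, 180)  # 0.5
#' @export
compute_cfs_ocp <- function(ocp_mmHg, cp_min_mmHg, cp_max_mmHg) {
  if (!(cp_min_mmHg < cp_max_mmHg)) stop("cp_min must be below cp_max")
  if (ocp_mmHg < cp_min_mmHg || ocp_mmHg > cp_max_mmHg) {
    stop("OCP outside the applied contact-pressure range")
  }
  (ocp_mmHg - cp_min_mmHg) / (cp_max_mmHg - cp_min_mmHg)
}

#' Pulse-amplitude-difference coefficient
#'
#' Splits the contact-pressure range 60--195 mmHg into five equal 27
#' mmHg sectors and compares the mean pulse amplitude in the deepest
#' sector with that in the shallowest:
#' `CFS_pad = H_deep / (H_deep + H_shallow)`, equivalently
#' `1/2 * (1 + (H_deep - H_shallow) / (H_deep + H_shallow))`. Bounded in
#' \\[0, 1\\]; 0.5 means equal shallow and deep amplitudes. In
#' `pairs_mode = "averaged"` the coefficient is additionally computed
#' from sectors 2 vs 4 and the two values averaged.
#'
#' @param envelope an `amplitude_envelope`.
#' @param sector_range_mmHg contact-pressure range to segment.
#' @param n_sectors number of equal-width sectors.
#' @param pairs_mode `"outer"` (sector 1 vs 5) or `"averaged"`
#'   (mean of the 1-5 and 2-4 comparisons).
#' @return list with `cfs_pad`, `h_shallow_mmHg`, `h_deep_mmHg`,
#'   `sector_bounds_mmHg`.
#' @examples
#' # H_deep = 3, H_shallow = 1 -> 0.75
#' @export
compute_cfs_pad <- function(envelope, sector_range_mmHg = c(60, 195),
                            n_sectors = 5,
                            pairs_mode = c("outer", "averaged")) {
  stopifnot(inherits(envelope, "amplitude_envelope"))
  pairs_mode <- match.arg(pairs_mode)
  bounds <- seq(sector_range_mmHg[1], sector_range_mmHg[2],
                length.out = n_sectors + 1)
  sector <- findInterval(envelope$cp_mmHg, bounds,
                         rightmost.closed = TRUE, all.inside = FALSE)
  in_range <- sector >= 1 & sector <= n_sectors
  h_mean <- vapply(seq_len(n_sectors), function(s) {
    a <- envelope$amplitude_mmHg[in_range & sector == s]
    if (!length(a)) NA_real_ else mean(a)
  }, numeric(1))

  pad_of <- function(lo, hi) {
    if (is.na(h_mean[lo])) stop(sprintf("no envelope points in CP sector %d (%.0f-%.0f mmHg)",
                                        lo, bounds[lo], bounds[lo + 1]))
    if (is.na(h_mean[hi])) stop(sprintf("no envelope points in CP sector %d (%.0f-%.0f mmHg)",
                                        hi, bounds[hi], bounds[hi + 1]))
    tot <- h_mean[hi] + h_mean[lo]
    if (tot <= 0) stop("H_deep + H_shallow is zero: CFS_pad undefined")
    h_mean[hi] / tot
  }

  cfs <- pad_of(1, n_sectors)
  if (pairs_mode == "averaged") {
    cfs <- mean(c(cfs, pad_of(2, n_sectors - 1)))
  }
  list(cfs_pad = cfs,
       h_shallow_mmHg = h_mean[1],
       h_deep_mmHg = h_mean[n_sectors],
       sector_bounds_mmHg = bounds)
}

#' Pulse depth index (PDI)
#'
#' The sensor displacement from the skin-contact point to the
#' displacement of maximal pulse amplitude:
#' `PDI = sd_optimal - sd_contact`, with `sd_optimal` read at the argmax
#' of the smoothed beat-by-beat envelope (same smoothing as
#' [compute_ocp()]; ties break toward the smallest displacement).
#' Defined only for the CETM protocol, which provides a continuous
#' displacement axis.
#'
#' @param envelope an `amplitude_envelope` (protocol `"cetm"`).
#' @param sd_contact_mm displacement at skin contact (actuator-origin),
#'   from [detect_contact_point()].
#' @param smooth_window smoothing window in beats.
#' @return list with `pdi_mm`, `sd_optimal_mm`, `boundary`.
#' @export
compute_pdi <- function(envelope, sd_contact_mm, smooth_window = 5) {
  stopifnot(inherits(envelope, "amplitude_envelope"))
  if (attr(envelope, "protocol") != "cetm") {
    stop("PDI requires the CETM protocol (continuous displacement axis)")
  }
  if (!is.finite(sd_contact_mm)) stop("sd_contact_mm must be finite")
  sm <- smooth_envelope(envelope$amplitude_mmHg, smooth_window)
  i <- which(sm >= max(sm) - 1e-12)[1]
  sd_opt <- envelope$sd_mm[i]
  list(pdi_mm = sd_opt - sd_contact_mm,
       sd_optimal_mm = sd_opt,
       boundary = i == 1 || i == nrow(envelope))
}
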