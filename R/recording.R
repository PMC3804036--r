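#' Construct a tonometry recording
#'
#' Container for one tonometric acquisition: a uniformly sampled
#' pressure signal plus the protocol metadata needed to interpret it.
#'
#' @param pressure_mmHg numeric vector of pressure samples.
#' @param fs_hz sampling rate, Hz.
#' @param protocol `"cetm"` (continuously evolving tonometric mechanism,
#'   constant-velocity advance) or `"stepwise"` (pressure-step holds).
#' @param velocity_mm_s actuator velocity (mandatory for `"cetm"`).
#' @param meta optional named list of additional metadata (e.g. step
#'   pressures and dwell for the stepwise protocol).
#' @return An object of class `tonometry_recording` with elements
#'   `time_s`, `pressure_mmHg`, `fs_hz`, `protocol`, `velocity_mm_s`,
#'   `meta`.
#' @export
tonometry_recording <- function(pressure_mmHg, fs_hz,
                                protocol = c("cetm", "stepwise"),
                                velocity_mm_s = NULL, meta = list()) {
  protocol <- match.arg(protocol)
  pressure_mmHg <- as.numeric(pressure_mmHg)
  if (length(pressure_mmHg) < 2) stop("recording needs at least 2 samples")
  if (any(!is.finite(pressure_mmHg))) stop("recording contains non-finite samples")
  if (!is.finite(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  if (protocol == "cetm") {
    if (is.null(velocity_mm_s) || !is.finite(velocity_mm_s) || velocity_mm_s <= 0) {
      stop("velocity_mm_s is mandatory and must be positive for protocol 'cetm'")
    }
  }
  rec <- list(
    time_s = (seq_along(pressure_mmHg) - 1) / fs_hz,
    pressure_mmHg = pressure_mmHg,
    fs_hz = as.numeric(fs_hz),
    protocol = protocol,
    velocity_mm_s = if (is.null(velocity_mm_s)) NA_real_ else as.numeric(velocity_mm_s),
    meta = meta
  )
  class(rec) <- "tonometry_recording"
  rec
}

#' @export
print.tonometry_recording <- function(x, ...) {
  cat(sprintf("Tonometry recording: %d samples, %.2f s at %g Hz, protocol '%s'\n",
              length(x$pressure_mmHg),
              length(x$pressure_mmHg) / x$fs_hz, x$fs_hz, x$protocol))
  if (x$protocol == "cetm") {
    cat(sprintf("  actuator velocity %.3f mm/s\n", x$velocity_mm_s))
  }
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}
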