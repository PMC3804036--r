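#' Fit the contact-pressure versus displacement relation
#'
#' Characterises the nonlinear CP--SD relation of a constant-velocity
#' tonometric recording (or any paired series): a least-squares
#' quadratic `CP = c0 + c1 SD + c2 SD^2` with its coefficient of
#' determination, and a power-law exponent estimated as the slope of
#' `log CP` on `log SD` over a window that excludes both the origin and
#' the sharply diverging near-occlusion regime. By default the window is
#' the upper half of the displacement range of the data (which the
#' caller should restrict to below occlusion).
#'
#' @param sd_mm displacement series, mm (strictly increasing).
#' @param cp_mmHg contact-pressure series, mmHg.
#' @param powerlaw_window_mm length-2 window `(lo, hi)` on `sd_mm` for
#'   the log-log fit; default upper half of the data range.
#' @return An object of class `cpsd_fit`: list with `quad_coeffs`
#'   (`c0`, `c1`, `c2`), `r2_quad`, `powerlaw_exponent`,
#'   `fit_window_sd_mm`, `data`.
#' @examples
#' sd <- seq(0.5, 5, by = 0.1)
#' fit <- cpsd_fit(sd, 1.5 * sd^2)
#' coef(fit)
#' fit$powerlaw_exponent  # 2
#' @export
cpsd_fit <- function(sd_mm, cp_mmHg, powerlaw_window_mm = NULL) {
  if (length(sd_mm) != length(cp_mmHg)) stop("sd and cp must have equal length")
  if (length(sd_mm) < 10) stop("need at least 10 paired samples")
  if (any(diff(sd_mm) <= 0)) stop("sd_mm must be strictly increasing")
  if (diff(range(sd_mm)) < .Machine$double.eps) stop("degenerate: constant sd")

  quad <- lm(cp_mmHg ~ sd_mm + I(sd_mm^2))
  co <- unname(coef(quad))
  ss_res <- sum(residuals(quad)^2)
  ss_tot <- sum((cp_mmHg - mean(cp_mmHg))^2)
  r2 <- 1 - ss_res / ss_tot

  if (is.null(powerlaw_window_mm)) {
    powerlaw_window_mm <- c(min(sd_mm) + diff(range(sd_mm)) / 2, max(sd_mm))
  }
  expo <- estimate_powerlaw_exponent(sd_mm, cp_mmHg, powerlaw_window_mm)

  structure(
    list(quad_coeffs = c(c0 = co[1], c1 = co[2], c2 = co[3]),
         r2_quad = r2,
         powerlaw_exponent = expo,
         fit_window_sd_mm = powerlaw_window_mm,
         data = data.frame(sd_mm = sd_mm, cp_mmHg = cp_mmHg),
         lm_fit = quad),
    class = "cpsd_fit"
  )
}

#' Power-law exponent of the CP--SD relation
#'
#' Ordinary least-squares slope of `log(cp)` on `log(sd)` within a
#' displacement window. The window must exclude `sd <= 0`; non-positive
#' contact pressures inside the window are an error.
#'
#' @param sd_mm displacement series, mm.
#' @param cp_mmHg contact-pressure series, mmHg.
#' @param window_mm length-2 displacement window `(lo, hi)`.
#' @return the exponent (dimensionless).
#' @export
estimate_powerlaw_exponent <- function(sd_mm, cp_mmHg, window_mm) {
  if (length(window_mm) != 2 || window_mm[1] >= window_mm[2]) {
    stop("window_mm must be (lo, hi) with lo < hi")
  }
  inw <- sd_mm >= window_mm[1] & sd_mm <= window_mm[2] & sd_mm > 0
  if (sum(inw) < 3) stop("fewer than 3 samples in the power-law window")
  if (any(cp_mmHg[inw] <= 0)) stop("non-positive contact pressure in the power-law window")
  fit <- lm(log(cp_mmHg[inw]) ~ log(sd_mm[inw]))
  unname(coef(fit)[2])
}

#' Extract the CP--SD series of a recording
#'
#' Convenience helper: decomposes a CETM recording, detects contact,
#' and returns the per-sample `(sd beyond contact, trend CP)` pairs over
#' the post-contact window, ready for [cpsd_fit()].
#'
#' @param recording a CETM [tonometry_recording()].
#' @param contact_time_s optional explicit contact time.
#' @return data frame with `sd_mm` (displacement beyond contact) and
#'   `cp_mmHg`.
#' @export
extract_cpsd <- function(recording, contact_time_s = NULL) {
  stopifnot(inherits(recording, "tonometry_recording"))
  if (recording$protocol != "cetm") stop("CP-SD extraction requires the CETM protocol")
  fs <- recording$fs_hz
  x <- recording$pressure_mmHg
  trend <- lowpass_filter(x, fs, 0.3)
  if (is.null(contact_time_s)) {
    contact_time_s <- detect_contact_point(recording, trend)$contact_time_s
  }
  t <- (seq_along(x) - 1) / fs
  post <- t > contact_time_s
  data.frame(sd_mm = recording$velocity_mm_s * (t[post] - contact_time_s),
             cp_mmHg = trend[post])
}

#' @export
coef.cpsd_fit <- function(object, ...) object$quad_coeffs

#' @export
predict.cpsd_fit <- function(object, sd_mm = NULL, ...) {
  if (is.null(sd_mm)) sd_mm <- object$data$sd_mm
  co <- object$quad_coeffs
  co[1] + co[2] * sd_mm + co[3] * sd_mm^2
}

#' @export
print.cpsd_fit <- function(x, ...) {
  co <- x$quad_coeffs
  cat("Contact-pressure vs displacement fit\n")
  cat(sprintf("  CP = %.3f + %.3f sd + %.3f sd^2   (R^2 = %.4f)\n",
              co[1], co[2], co[3], x$r2_quad))
  cat(sprintf("  power-law exponent %.3f on sd in [%.2f, %.2f] mm\n",
              x$powerlaw_exponent, x$fit_window_sd_mm[1], x$fit_window_sd_mm[2]))
  invisible(x)
}

#' @export
plot.cpsd_fit <- function(x, ...) {
  d <- x$data
  plot(d$sd_mm, d$cp_mmHg, pch = 16, cex = 0.4,
       xlab = "sensor displacement (mm)", ylab = "contact pressure (mmHg)",
       main = "CP-SD relation", ...)
  lines(d$sd_mm, predict(x), col = 2, lwd = 2)
  abline(v = x$fit_window_sd_mm, lty = 3, col = 4)
  legend("topleft", bty = "n",
         legend = c("data", "quadratic fit",
                    sprintf("power-law window (exponent %.2f)", x$powerlaw_exponent)),
         col = c(1, 2, 4), lty = c(NA, 1, 3), pch = c(16, NA, NA))
  invisible(x)
}
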