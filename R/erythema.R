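# Reference irradiance defining one UVI unit, mW m^-2
uvi_reference <- 25

#' The erythema action spectrum (ISO/CIE 17166:2019)
#'
#' Relative sensitivity of human skin to sunburn at each wavelength:
#' \deqn{w(\lambda) = 1, \quad 250 \le \lambda \le 298}
#' \deqn{w(\lambda) = 10^{0.094(298-\lambda)}, \quad 298 < \lambda \le 328}
#' \deqn{w(\lambda) = 10^{0.015(140-\lambda)}, \quad 328 < \lambda \le 400}
#' Outside 250-400 nm the weight is zero by convention (the standard does not
#' define it there). The two branch changes are continuous: both formulas give
#' 1 at 298 nm and 10^-2.82 at 328 nm.
#'
#' @param wavelength Numeric vector, nm.
#' @return Dimensionless weights in `[0, 1]`.
#' @examples
#' erythema_weight(c(298, 310, 328))
#' @export
erythema_weight <- function(wavelength) {
  w <- numeric(length(wavelength))
  inb <- !is.na(wavelength) & wavelength >= 250 & wavelength <= 400
  l <- wavelength[inb]
  w[inb] <- ifelse(l <= 298, 1,
            ifelse(l <= 328, 10^(0.094 * (298 - l)),
                             10^(0.015 * (140 - l))))
  w
}

#' Erythema action spectrum as a weight curve on a grid
#'
#' @param grid Wavelength grid, nm (default: 250-400 nm at 0.5 nm).
#' @return A weight-curve tibble (`wavelength`, `weight`).
#' @export
erythema_action_spectrum <- function(grid = full_uv_grid()) {
  weight_curve(grid, erythema_weight(grid))
}

#' Compute the UV Index of a spectrum
#'
#' The UVI is the erythemally weighted irradiance integral divided by the
#' reference value of 25 mW m^-2:
#' \deqn{UVI = \frac{1}{25}\int w(\lambda)\, I(\lambda)\, d\lambda}
#' integrated (trapezoid rule) over the spectrum's own grid intersected with
#' 250-400 nm. No extrapolation beyond the measured range is performed; when
#' the grid does not cover 250-400 nm (e.g. Brewer instruments stop at
#' 363 nm) the result carries attribute `truncated = TRUE`. The missing UV-A
#' tail is worth roughly 1-3 % of the total for solar spectra.
#'
#' @param spec Spectrum data frame (`wavelength` nm, `irradiance` mW m^-2 nm^-1).
#' @return UVI, a non-negative number (attribute `truncated` flags incomplete
#'   coverage of 250-400 nm).
#' @examples
#' sp <- spectrum(seq(250, 400, 0.5), rep(25, 301))
#' compute_uvi(sp) # about 52.65
#' @export
compute_uvi <- function(spec) {
  e <- erythemal_irradiance(spec)
  structure(as.numeric(e) / uvi_reference, truncated = attr(e, "truncated"))
}

#' Erythemally weighted irradiance of a spectrum
#'
#' The erythema-weighted integral in mW m^-2; equal to 25 times the UVI.
#'
#' @inheritParams compute_uvi
#' @return Erythemal irradiance, mW m^-2.
#' @export
erythemal_irradiance <- function(spec) {
  check_spectrum(spec, min_points = 2L)
  w <- erythema_weight(spec$wavelength)
  val <- sum(trapezoid_weights(spec$wavelength) * spec$irradiance * w)
  truncated <- min(spec$wavelength) > 250 || max(spec$wavelength) < 400
  structure(val, truncated = truncated)
}
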