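# Ozone column of one Dobson Unit, molecules cm^-2: a 0.001 cm layer at
# standard temperature and pressure, N_A / 22400 cm^3 mol^-1 molecules per cm^3.
molecules_per_du <- 0.001 * 6.02214076e23 / 22400

#' Dobson-unit conversions for ozone columns
#'
#' One Dobson Unit (DU) is the ozone column forming a 0.001 cm layer of pure
#' ozone at standard temperature and pressure, i.e. about 2.6885e16
#' molecules cm^-2; equivalently DU = 3.720e-17 times the column in
#' molecules cm^-2. The two functions are exact inverses.
#'
#' @param z Ozone column, molecules cm^-2 (non-negative).
#' @param du Ozone column, Dobson Units (non-negative).
#' @return The converted column.
#' @examples
#' dobson_from_column(2.6885e16) # about 1 DU
#' column_from_dobson(300)       # about 8.07e18
#' @export
dobson_from_column <- function(z) {
  if (any(z < 0, na.rm = TRUE)) stop("Ozone column must be non-negative.", call. = FALSE)
  z / molecules_per_du
}

#' @rdname dobson_from_column
#' @export
column_from_dobson <- function(du) {
  if (any(du < 0, na.rm = TRUE)) stop("Ozone column must be non-negative.", call. = FALSE)
  du * molecules_per_du
}

#' Bundle reference curves for the single-layer atmospheric model
#'
#' The model needs two wavelength-dependent references: the extraterrestrial
#' (AM0) solar spectrum and the ozone absorption cross-section. By default
#' both are the package's built-in smooth approximations (see
#' [synth_solar_spectrum()] and [synth_ozone_cross_section()]); supply
#' measured tables to override, e.g. read with [read_spectrum_table()].
#'
#' @param solar Optional spectrum data frame (`wavelength` nm, `irradiance`
#'   mW m^-2 nm^-1) for the AM0 solar spectrum.
#' @param sigma Optional data frame (`wavelength` nm, `sigma` cm^2/molecule)
#'   for the ozone cross-section. Values must be positive and decreasing over
#'   290-340 nm (Huggins-band behaviour).
#' @return An object of class `uvi_refs`.
#' @export
reference_curves <- function(solar = NULL, sigma = NULL) {
  if (!is.null(solar)) check_spectrum(solar, min_points = 2L)
  if (!is.null(sigma)) {
    if (!all(c("wavelength", "sigma") %in% names(sigma))) {
      stop("`sigma` must have `wavelength` and `sigma` columns.", call. = FALSE)
    }
    if (any(sigma$sigma <= 0)) {
      stop("Ozone cross-section values must be positive.", call. = FALSE)
    }
    hug <- sigma$wavelength >= 290 & sigma$wavelength <= 340
    if (sum(hug) >= 2 && any(diff(sigma$sigma[hug]) >= 0)) {
      stop("Ozone cross-section must decrease over 290-340 nm.", call. = FALSE)
    }
  }
  structure(list(solar = solar, sigma = sigma), class = "uvi_refs")
}

#' @export
print.uvi_refs <- function(x, ...) {
  src <- function(tab) if (is.null(tab)) "built-in synthetic" else
    sprintf("table (%d points, %.1f-%.1f nm)", nrow(tab),
            min(tab$wavelength), max(tab$wavelength))
  cat("Reference curves for the single-layer atmospheric model\n")
  cat("  solar AM0 spectrum:   ", src(x$solar), "\n")
  cat("  ozone cross-section:  ", src(x$sigma), "\n")
  invisible(x)
}

# internal: evaluate reference curves on a grid (closed forms when synthetic)
resolve_refs <- function(refs, grid) {
  if (!inherits(refs, "uvi_refs")) {
    stop("`refs` must be created with reference_curves().", call. = FALSE)
  }
  solar <- if (is.null(refs$solar)) {
    synth_solar_value(grid)
  } else {
    rng <- range(refs$solar$wavelength)
    if (min(grid) < rng[1] || max(grid) > rng[2]) {
      stop("Solar reference table does not cover the requested grid.", call. = FALSE)
    }
    stats::approx(refs$solar$wavelength, refs$solar$irradiance, xout = grid)$y
  }
  sigma <- if (is.null(refs$sigma)) {
    synth_sigma_value(grid)
  } else {
    rng <- range(refs$sigma$wavelength)
    if (min(grid) < rng[1] || max(grid) > rng[2]) {
      stop("Ozone cross-section table does not cover the requested grid.", call. = FALSE)
    }
    stats::approx(refs$sigma$wavelength, refs$sigma$sigma, xout = grid)$y
  }
  list(solar = solar, sigma = sigma)
}

# internal: validate a single parameter set (A, B, z_du, phi_deg)
check_params <- function(params) {
  params <- as.list(params)
  need <- c("A", "B", "z_du", "phi_deg")
  if (!all(need %in% names(params))) {
    stop("Model parameters need named entries A, B, z_du, phi_deg.", call. = FALSE)
  }
  p <- lapply(params[need], as.numeric)
  if (p$A < 0) stop("Aerosol loss A must be >= 0.", call. = FALSE)
  if (p$z_du < 0) stop("Ozone column z_du must be >= 0.", call. = FALSE)
  if (p$phi_deg < 0 || p$phi_deg >= 90) {
    stop("Solar zenith angle must satisfy 0 <= phi < 90 degrees ",
         "(the slant path diverges at the horizon).", call. = FALSE)
  }
  p
}

# internal: n x p matrix of model spectra for vectors of parameters
huber_matrix <- function(A, B, z_du, phi_deg, solar, sigma, grid) {
  mu <- cos(phi_deg * pi / 180)
  slant <- column_from_dobson(z_du) / mu
  n <- length(A)
  expo <- outer(-A, rep(1, length(grid))) + outer(B, grid - 320) - outer(slant, sigma)
  exp(expo) * matrix(solar, n, length(grid), byrow = TRUE)
}

#' Single-layer atmospheric forward model for surface UV irradiance
#'
#' Surface spectral irradiance as an extraterrestrial solar spectrum
#' attenuated by a single atmospheric layer with three adjustable parameters:
#' \deqn{I(\lambda) = \exp\!\left[-A + B(\lambda - 320) -
#'   \frac{z\,\sigma(\lambda)}{\cos\varphi}\right] I_{solar}(\lambda)}
#' where `A` (dimensionless, >= 0) is gray aerosol/cloud loss, `B` (nm^-1)
#' grossly captures the wavelength dependence of scattering, `z` is the ozone
#' column and `sigma` the ozone absorption cross-section; the 1/cos(phi)
#' factor lengthens the optical path through the ozone layer at solar zenith
#' angle phi.
#'
#' @param params Named list or one-row data frame with `A` (dimensionless),
#'   `B` (nm^-1), `z_du` (ozone column, Dobson Units) and `phi_deg`
#'   (solar zenith angle, degrees, in `[0, 90)`).
#' @param refs Reference curves from [reference_curves()].
#' @param grid Wavelength grid, nm.
#' @return A spectrum tibble on `grid`, mW m^-2 nm^-1.
#' @examples
#' huber_forward(list(A = 1, B = 0.002, z_du = 300, phi_deg = 30))
#' @export
huber_forward <- function(params, refs = reference_curves(), grid = brewer_grid()) {
  p <- check_params(params)
  rc <- resolve_refs(refs, grid)
  irr <- huber_matrix(p$A, p$B, p$z_du, p$phi_deg, rc$solar, rc$sigma, grid)[1, ]
  tibble::tibble(wavelength = grid, irradiance = irr)
}

#' Log-linear least-squares fit of the single-layer model
#'
#' Taking logs of the forward model makes it linear in (A, B, z): ordinary
#' least squares of `log(I / I_solar)` on the regressors
#' `{-1, lambda - 320, -sigma(lambda)/cos(phi)}` recovers the parameters
#' exactly on noiseless model spectra. Used both as a fast estimator and as
#' the initializer (and independent cross-check) for [fit_huber()].
#'
#' Channels with irradiance at or below `min_irradiance` are dropped (and
#' counted in the result): near the instrument noise floor the log-ratio is
#' dominated by noise.
#'
#' @param spec Spectrum data frame.
#' @param refs Reference curves from [reference_curves()].
#' @param phi_deg Solar zenith angle, degrees (known metadata, not fitted).
#' @param min_irradiance Channels at or below this irradiance (mW m^-2 nm^-1)
#'   are excluded from the fit.
#' @return A `huber_fit` object; see [fit_huber()].
#' @export
loglinear_fit <- function(spec, refs = reference_curves(), phi_deg,
                          min_irradiance = 0.1) {
  check_spectrum(spec, min_points = 3L)
  if (phi_deg < 0 || phi_deg >= 90) stop("phi_deg must be in [0, 90).", call. = FALSE)
  rc <- resolve_refs(refs, spec$wavelength)
  mu <- cos(phi_deg * pi / 180)
  ok <- spec$irradiance > min_irradiance & rc$solar > 0
  n_dropped <- sum(!ok)
  if (sum(ok) < 3) {
    stop("Fewer than 3 usable channels (3 free parameters).", call. = FALSE)
  }
  y <- log(spec$irradiance[ok] / rc$solar[ok])
  X <- cbind(-1, spec$wavelength[ok] - 320, -rc$sigma[ok] / mu)
  co <- qr.coef(qr(X), y)
  pred <- drop(X %*% co)
  new_huber_fit(
    A = unname(co[1]), B = unname(co[2]),
    z_du = dobson_from_column(unname(co[3])),
    phi_deg = phi_deg,
    rms = sqrt(mean((exp(pred) * rc$solar[ok] - spec$irradiance[ok])^2)),
    converged = TRUE, n_channels = sum(ok), n_dropped = n_dropped,
    method = "loglinear"
  )
}

#' Fit the single-layer atmospheric model to a measured spectrum
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) of the
#' forward model against the spectrum, with residuals in linear irradiance
#' space, initialized from [loglinear_fit()] and constrained to `A >= 0`,
#' `z >= 0`. The solar zenith angle is known metadata, not a fitted
#' parameter.
#'
#' @inheritParams loglinear_fit
#' @return An object of class `huber_fit`: fitted `A`, `B` (nm^-1), `z_du`
#'   (DU), plus residual RMS (mW m^-2 nm^-1), a convergence flag and channel
#'   counts. Use [generics::tidy()] / [generics::glance()] to extract tables.
#' @examples
#' truth <- list(A = 1, B = 0.002, z_du = 300, phi_deg = 30)
#' sp <- huber_forward(truth)
#' fit_huber(sp, phi_deg = 30)
#' @export
fit_huber <- function(spec, refs = reference_curves(), phi_deg,
                      min_irradiance = 0.1) {
  check_spectrum(spec, min_points = 3L)
  init <- loglinear_fit(spec, refs, phi_deg, min_irradiance = min_irradiance)
  rc <- resolve_refs(refs, spec$wavelength)
  grid <- spec$wavelength
  obs <- spec$irradiance
  resid_fun <- function(par) {
    huber_matrix(par[1], par[2], par[3], phi_deg, rc$solar, rc$sigma, grid)[1, ] - obs
  }
  start <- c(A = max(init$A, 0), B = init$B, z_du = max(init$z_du, 0))
  res <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(0, -Inf, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  converged <- res$info %in% 1:4
  if (!converged) {
    warning("Levenberg-Marquardt did not converge (info = ", res$info, ").",
            call. = FALSE)
  }
  new_huber_fit(
    A = unname(res$par[1]), B = unname(res$par[2]), z_du = unname(res$par[3]),
    phi_deg = phi_deg,
    rms = sqrt(mean(res$fvec^2)),
    converged = converged, n_channels = length(obs),
    n_dropped = init$n_dropped, method = "levenberg-marquardt"
  )
}

new_huber_fit <- function(A, B, z_du, phi_deg, rms, converged, n_channels,
                          n_dropped, method) {
  structure(
    list(A = A, B = B, z_du = z_du, phi_deg = phi_deg, rms = rms,
         converged = converged, n_channels = n_channels,
         n_dropped = n_dropped, method = method),
    class = "huber_fit"
  )
}

#' @export
print.huber_fit <- function(x, ...) {
  cat("Single-layer atmospheric model fit (", x$method, ")\n", sep = "")
  cat(sprintf("  A = %.5g, B = %.5g nm^-1, z = %.5g DU (phi = %.3g deg)\n",
              x$A, x$B, x$z_du, x$phi_deg))
  cat(sprintf("  residual RMS %.4g mW/m^2/nm over %d channels; converged: %s\n",
              x$rms, x$n_channels, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single-layer model fit
#'
#' @param x A `huber_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with its unit; `glance()`: one row
#'   of fit diagnostics.
#' @method tidy huber_fit
#' @export
tidy.huber_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "B", "z_du"),
    estimate = c(x$A, x$B, x$z_du),
    unit = c("dimensionless", "nm^-1", "DU")
  )
}

#' @rdname tidy.huber_fit
#' @method glance huber_fit
#' @export
glance.huber_fit <- function(x, ...) {
  tibble::tibble(
    rms = x$rms, converged = x$converged, n_channels = x$n_channels,
    n_dropped = x$n_dropped, phi_deg = x$phi_deg, method = x$method
  )
}

#' Ozone column at which the 310 nm rule switches to underestimation
#'
#' The linear rule `UVI = 77 I310` (I310 in W m^-2 nm^-1) underestimates the
#' true UVI when the ozone column is low (ozone-hole conditions): short
#' erythemal wavelengths then penetrate and raise the UVI faster than the
#' 310 nm channel. This helper reports the crossover column, as a function of
#' the spectral-tilt parameter and zenith angle, at which the rule is exact;
#' below it the rule underestimates. The gray-loss parameter A cancels from
#' the ratio and plays no role.
#'
#' @param phi_deg Solar zenith angle, degrees.
#' @param B Spectral-tilt parameter, nm^-1.
#' @param refs Reference curves from [reference_curves()].
#' @param uvi_per_w Rule constant, UVI per (W m^-2 nm^-1); default 77.
#' @param interval Ozone search interval, DU.
#' @param grid Wavelength grid for the full-range UVI.
#' @return Crossover ozone column in DU, or `NA` if the rule never crosses
#'   within `interval`.
#' @export
crossover_ozone <- function(phi_deg, B = 0, refs = reference_curves(),
                            uvi_per_w = 77, interval = c(50, 600),
                            grid = full_uv_grid()) {
  f <- function(z_du) {
    sp <- huber_forward(list(A = 0, B = B, z_du = z_du, phi_deg = phi_deg),
                        refs, grid)
    i310 <- stats::approx(sp$wavelength, sp$irradiance, xout = 310)$y / 1000
    uvi_per_w * i310 / as.numeric(compute_uvi(sp)) - 1
  }
  lo <- f(interval[1]); hi <- f(interval[2])
  if (sign(lo) == sign(hi)) return(NA_real_)
  stats::uniroot(f, interval, tol = 0.01)$root
}
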