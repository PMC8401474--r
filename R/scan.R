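#' Per-wavelength single-channel calibration scan
#'
#' Treats every wavelength channel as an ideally calibrated linear
#' single-wavelength detector: for each channel, fits OLS of true UVI on the
#' channel irradiance (with intercept), computes the signed percent error of
#' the calibrated estimate per spectrum, and summarises the median absolute
#' percent error and the accuracy at a tolerance. The wavelength minimising
#' the median error is the scan optimum; for solar ensembles spanning
#' realistic ozone and zenith-angle variation it falls in a sharp, narrow
#' band near 310 nm.
#'
#' Channels whose irradiance is constant across the ensemble cannot be
#' calibrated (singular regression); they are flagged `excluded` and ignored
#' when locating the optimum. If every channel is excluded (e.g. one spectrum
#' duplicated) the scan is degenerate: intercept-only calibration is then
#' exact and all errors are zero.
#'
#' @param ensemble Ensemble tibble with a `spectrum` list-column and a `uvi`
#'   column (see [generate_ensemble()]); at least 10 spectra with positive
#'   UVI are required, spectra with UVI <= 0 are dropped with a message.
#' @param tolerance Accuracy tolerance, percent.
#' @return A tibble of class `uvi_scan`, one row per channel: `wavelength`,
#'   `slope` (UVI per mW m^-2 nm^-1; multiply by 1000 for the
#'   per-(W m^-2 nm^-1) scale usual in print), `intercept` (UVI),
#'   `r_squared`, `median_abs_error` (%), `accuracy` (%) and `excluded`.
#'   Attributes: `best_wavelength` (lowest-wavelength argmin of the median
#'   error over non-excluded channels), `tolerance`, `degenerate`.
#' @seealso [best_wavelength()], [autoplot.uvi_scan()]
#' @export
scan_wavelengths <- function(ensemble, tolerance = 10) {
  me <- ensemble_matrix(ensemble)
  u <- ensemble$uvi
  keep <- u > 0
  if (any(!keep)) {
    message("Dropped ", sum(!keep), " spectra with non-positive UVI.")
  }
  u <- u[keep]
  x_all <- me$irradiance[keep, , drop = FALSE]
  if (length(u) < 10) {
    stop("At least 10 spectra with positive UVI are required.", call. = FALSE)
  }
  n <- length(u)
  p <- ncol(x_all)

  xbar <- colMeans(x_all)
  ubar <- mean(u)
  xc <- sweep(x_all, 2, xbar)
  sxx <- colSums(xc^2)
  sxu <- as.numeric(crossprod(xc, u - ubar))
  suu <- sum((u - ubar)^2)
  excluded <- sxx <= 0
  slope <- ifelse(excluded, NA_real_, sxu / sxx)
  intercept <- ifelse(excluded, ubar, ubar - slope * xbar)
  r2 <- ifelse(excluded, NA_real_,
               if (suu == 0) 1 else (sxu^2) / (sxx * suu))
  # percent errors per channel; excluded channels use intercept-only estimate
  pred <- sweep(x_all, 2, slope, `*`)
  pred[, excluded] <- 0
  pred <- sweep(pred, 2, intercept, `+`)
  err <- 100 * (pred / u - 1)
  mede <- apply(abs(err), 2, stats::median)
  acc <- 100 * colMeans(abs(err) <= tolerance)

  degenerate <- all(excluded) || suu == 0
  usable <- which(!excluded)
  best <- if (length(usable)) {
    me$grid[usable[which.min(mede[usable])]]
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    wavelength = me$grid, slope = slope, intercept = intercept,
    r_squared = r2, median_abs_error = mede, accuracy = acc,
    excluded = excluded
  )
  structure(out,
            class = c("uvi_scan", class(tibble::tibble())),
            best_wavelength = best, tolerance = tolerance,
            degenerate = degenerate, n_spectra = n)
}

#' Optimum wavelength of a calibration scan
#'
#' @param scan A `uvi_scan` object from [scan_wavelengths()].
#' @return The wavelength (nm) with the lowest median absolute percent error
#'   (lowest-wavelength tie-break), or `NA` for a fully degenerate scan.
#' @export
best_wavelength <- function(scan) {
  stopifnot(inherits(scan, "uvi_scan"))
  attr(scan, "best_wavelength")
}

#' UVI-normalized spectral collapse
#'
#' Weights each spectrum by the erythema action spectrum and divides by its
#' own UVI (units mW m^-2 nm^-1 per UVI). However variable the raw spectra,
#' these normalized curves collapse nearly to a point at one wavelength; the
#' per-wavelength coefficient of variation (CV) locates that collapse point,
#' the graphical counterpart of the [scan_wavelengths()] optimum.
#'
#' Spectra with UVI at or below `uvi_min` (default 0.5, dim or twilight
#' conditions where the relative error is dominated by the noise floor) are
#' excluded first.
#'
#' @param ensemble Ensemble tibble with `spectrum` and `uvi` columns.
#' @param uvi_min UVI filter threshold; spectra with `uvi > uvi_min` are kept.
#' @return An object of class `uvi_collapse`: list with `curves` (long tibble
#'   `id`, `wavelength`, `value`), `cv` (tibble `wavelength`, `cv`),
#'   `collapse_wavelength` (argmin of CV, lowest-wavelength tie-break),
#'   `n_used` and `uvi_min`.
#' @export
normalized_collapse <- function(ensemble, uvi_min = 0.5) {
  me <- ensemble_matrix(ensemble)
  keep <- ensemble$uvi > uvi_min
  if (!any(keep)) {
    stop("No spectra with UVI > ", uvi_min, ".", call. = FALSE)
  }
  u <- ensemble$uvi[keep]
  ids <- ensemble$id[keep]
  w <- erythema_weight(me$grid)
  norm <- sweep(me$irradiance[keep, , drop = FALSE], 2, w, `*`) / u
  mu <- colMeans(norm)
  cv <- ifelse(mu > 0,
               apply(norm, 2, stats::sd) / mu,
               NA_real_)
  curves <- tibble::tibble(
    id = rep(ids, each = length(me$grid)),
    wavelength = rep(me$grid, times = length(ids)),
    value = as.numeric(t(norm))
  )
  ok <- which(!is.na(cv))
  structure(
    list(curves = curves,
         cv = tibble::tibble(wavelength = me$grid, cv = cv),
         collapse_wavelength = if (length(ok)) me$grid[ok[which.min(cv[ok])]] else NA_real_,
         n_used = length(u), uvi_min = uvi_min),
    class = "uvi_collapse"
  )
}

#' @export
print.uvi_collapse <- function(x, ...) {
  cat(sprintf("UVI-normalized collapse of %d spectra (UVI > %g)\n",
              x$n_used, x$uvi_min))
  cat(sprintf("  collapse point (minimum CV): %.1f nm, CV = %.4f\n",
              x$collapse_wavelength,
              x$cv$cv[x$cv$wavelength == x$collapse_wavelength]))
  invisible(x)
}
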