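#' Model the output of a radiometer with a given spectral sensitivity
#'
#' The detector signal is the sensitivity-weighted irradiance integral
#' `M = integral s(lambda) I(lambda) dlambda` (mW m^-2 for a dimensionless
#' sensitivity). A detector whose sensitivity equals the erythema action
#' spectrum reads exactly 25 times the UVI.
#'
#' @param spec Spectrum data frame.
#' @param sensitivity Weight-curve data frame (`wavelength`, `weight`).
#' @return Signal, mW m^-2.
#' @export
detector_current <- function(spec, sensitivity) {
  integrate_product(spec, sensitivity)
}

#' Built-in detector sensitivity curves
#'
#' Analytically defined sensitivities used in detector comparisons:
#' `"eas"` (the erythema action spectrum), `"boxcar"` (an ideal narrow
#' bandpass of height 1, `center` +/- `width`/2), `"flatband"` (flat bandpass
#' between `lo` and `hi`, e.g. a 300-400 nm broad-band design) and
#' for the two band shapes, grid points exactly on a band edge carry half
#' weight, so the trapezoid-integrated equivalent width equals the nominal
#' width;
#' `"from_table"` (an arbitrary measured curve, e.g. a digitized vendor
#' datasheet, read from a two-column file).
#'
#' @param name One of `"eas"`, `"boxcar"`, `"flatband"`, `"from_table"`.
#' @param grid Wavelength grid, nm, on which the curve is evaluated.
#' @param center,width Boxcar center and full width, nm.
#' @param lo,hi Flat band edges, nm.
#' @param path File for `"from_table"`, read with [read_spectrum_table()]
#'   (interpolated onto `grid`, zero outside the tabulated range).
#' @return A weight-curve tibble.
#' @examples
#' builtin_sensitivity("boxcar", center = 310, width = 1)
#' @export
builtin_sensitivity <- function(name = c("eas", "boxcar", "flatband", "from_table"),
                                grid = brewer_grid(), center = 310, width = 1,
                                lo = 300, hi = 400, path = NULL) {
  name <- match.arg(name)
  band <- function(a, b) {
    # half weight exactly at the band edges so that the trapezoid-rule
    # equivalent width equals the nominal width b - a; an edge coinciding
    # with the grid boundary keeps full weight (no ramp beyond the grid)
    inside <- as.numeric(grid > a & grid < b)
    inside[grid == a] <- if (a > grid[1]) 0.5 else 1
    inside[grid == b] <- if (b < grid[length(grid)]) 0.5 else 1
    inside
  }
  w <- switch(name,
    eas = erythema_weight(grid),
    boxcar = band(center - width / 2, center + width / 2),
    flatband = band(lo, hi),
    from_table = {
      if (is.null(path)) stop("`path` is required for from_table.", call. = FALSE)
      tab <- read_spectrum_table(path, value_name = "weight")
      interp_zero(tab$wavelength, tab$weight, grid)
    }
  )
  weight_curve(grid, w)
}

#' Fit a linear UVI calibration for a detector
#'
#' Ordinary least squares of true UVI on detector signal with an intercept:
#' `U = C0 + C1 M`. The fitted coefficients convert any signal into a UVI
#' estimate via [predict()].
#'
#' @param signal Numeric vector of detector signals M (mW m^-2).
#' @param uvi Numeric vector of true UVI values, same length.
#' @return An object of class `uvi_calibration` with coefficients `c0` (UVI)
#'   and `c1` (UVI per mW m^-2), `n` and `r_squared`. [generics::tidy()] and
#'   [generics::glance()] methods are provided.
#' @examples
#' cal <- fit_calibration(signal = c(1, 2, 3), uvi = c(3, 5, 7))
#' predict(cal, signal = 4) # 9
#' @export
fit_calibration <- function(signal, uvi) {
  if (length(signal) != length(uvi)) {
    stop("`signal` and `uvi` must have the same length.", call. = FALSE)
  }
  if (length(signal) < 2) stop("At least 2 observations are required.", call. = FALSE)
  if (stats::var(signal) == 0) {
    stop("Constant detector signal: calibration design is singular.", call. = FALSE)
  }
  fit <- stats::lm(uvi ~ signal)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((uvi - mean(uvi))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(c0 = unname(stats::coef(fit)[1]), c1 = unname(stats::coef(fit)[2]),
         n = length(signal), r_squared = min(max(r2, 0), 1)),
    class = "uvi_calibration"
  )
}

#' @export
print.uvi_calibration <- function(x, ...) {
  cat(sprintf("Linear UVI calibration: U = %.6g + %.6g M  (n = %d, R^2 = %.4f)\n",
              x$c0, x$c1, x$n, x$r_squared))
  invisible(x)
}

#' @export
predict.uvi_calibration <- function(object, signal, ...) {
  object$c0 + object$c1 * signal
}

#' Tidy a linear UVI calibration
#'
#' @param x A `uvi_calibration` object.
#' @param ... Unused.
#' @return `tidy()`: coefficient table; `glance()`: one-row fit summary.
#' @method tidy uvi_calibration
#' @export
tidy.uvi_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("c0", "c1"),
    estimate = c(x$c0, x$c1),
    unit = c("UVI", "UVI per mW m^-2")
  )
}

#' @rdname tidy.uvi_calibration
#' @method glance uvi_calibration
#' @export
glance.uvi_calibration <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n)
}

#' Signed percent error of calibrated UVI estimates
#'
#' `epsilon = 100 * (C(M)/U - 1)` for each observation; the calibrated
#' estimate relative to the true UVI. Observations with non-positive true UVI
#' are excluded (`NA`) with a message, since the relative error is undefined.
#'
#' @param model A `uvi_calibration` object.
#' @param signal Detector signals, mW m^-2.
#' @param uvi True UVI values (> 0).
#' @return Signed percent errors.
#' @export
percent_error <- function(model, signal, uvi) {
  stopifnot(inherits(model, "uvi_calibration"))
  bad <- uvi <= 0
  if (any(bad)) {
    message("Excluded ", sum(bad), " observation(s) with non-positive UVI.")
  }
  err <- 100 * (predict(model, signal) / uvi - 1)
  err[bad] <- NA_real_
  err
}

#' Accuracy curve: percentage of spectra within an error tolerance
#'
#' The empirical cumulative distribution of absolute percent error:
#' `A(t) = 100 * fraction(|epsilon| <= t)`, evaluated on a tolerance grid.
#' Non-decreasing in `t` and reaching 100 at the maximum absolute error.
#' Absolute (not signed) error is used: a detector that underestimates by 50 %
#' is not "within 10 %".
#'
#' @param errors Signed percent errors (NAs dropped).
#' @param tolerances Tolerance grid, percent.
#' @return A tibble of class `uvi_accuracy` with columns `tolerance` and
#'   `accuracy` (percent of spectra, in `[0, 100]`).
#' @examples
#' accuracy_curve(c(-5, 5, 15), tolerances = c(0, 10, 20))
#' @export
accuracy_curve <- function(errors, tolerances = seq(0, 50, by = 0.5)) {
  errors <- errors[!is.na(errors)]
  if (!length(errors)) stop("No errors to summarise.", call. = FALSE)
  acc <- vapply(tolerances, function(t) 100 * mean(abs(errors) <= t), 0)
  structure(tibble::tibble(tolerance = tolerances, accuracy = acc),
            class = c("uvi_accuracy", "tbl_df", "tbl", "data.frame"))
}

#' Compare detector designs on a spectral ensemble
#'
#' For each detector: computes its signal under every spectrum, fits its own
#' best linear calibration against the true UVI, and tabulates the median
#' signal (absolute, and relative to the erythema-matched detector), the
#' median absolute percent error and the accuracy at a tolerance (default
#' 10 %). An erythema-matched detector has exactly zero error and 100 %
#' accuracy by construction (its signal is 25 times the UVI), and multiplying
#' any sensitivity by a positive constant changes only the signal column.
#'
#' The relative-signal column is the literal ratio of median signals
#' median(M_d) / median(M_eas); an erythema detector reads roughly twice a
#' 1 nm 310 nm boxcar, since 25 x UVI is about 1.9 x I310 per nm.
#'
#' @param ensemble Ensemble tibble (see [generate_ensemble()]); the `uvi`
#'   column is the calibration truth.
#' @param detectors Named list of weight-curve data frames. Default: the
#'   erythema action spectrum, a 310 +/- 0.5 nm boxcar, and a flat 300-400 nm
#'   broad band, all on the ensemble grid.
#' @param tolerance Accuracy tolerance, percent.
#' @return A tibble with one row per detector.
#' @export
evaluate_detectors <- function(ensemble, detectors = NULL, tolerance = 10) {
  me <- ensemble_matrix(ensemble)
  if (nrow(me$irradiance) < 2) stop("At least 2 spectra are required.", call. = FALSE)
  if (is.null(detectors)) {
    detectors <- list(
      eas = builtin_sensitivity("eas", grid = me$grid),
      `310nm boxcar` = builtin_sensitivity("boxcar", grid = me$grid,
                                           center = 310, width = 1),
      `broad band` = builtin_sensitivity("flatband", grid = me$grid,
                                         lo = 300, hi = 400)
    )
  }
  if (!length(detectors)) stop("At least one detector is required.", call. = FALSE)
  if (is.null(names(detectors)) || any(!nzchar(names(detectors)))) {
    stop("`detectors` must be a named list.", call. = FALSE)
  }
  tw <- trapezoid_weights(me$grid)
  uvi <- ensemble$uvi
  signal_for <- function(curve) {
    w <- interp_zero(curve$wavelength, curve$weight, me$grid)
    as.numeric(me$irradiance %*% (tw * w))
  }
  eas_median <- stats::median(signal_for(erythema_action_spectrum(me$grid)))
  rows <- purrr::imap(detectors, function(curve, nm) {
    m <- signal_for(curve)
    cal <- fit_calibration(m, uvi)
    err <- percent_error(cal, m, uvi)
    tibble::tibble(
      detector = nm,
      median_signal = stats::median(m),
      median_signal_rel_eas = stats::median(m) / eas_median,
      median_abs_error_pct = stats::median(abs(err), na.rm = TRUE),
      accuracy_pct = 100 * mean(abs(err) <= tolerance, na.rm = TRUE),
      r_squared = cal$r_squared
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "tolerance") <- tolerance
  out
}
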