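#' Plot a wavelength-scan error curve
#'
#' Median absolute percent calibration error of an ideal single-wavelength
#' detector against its wavelength, with the optimum marked.
#'
#' @param object A `uvi_scan` from [scan_wavelengths()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uvi_scan
#' @export
autoplot.uvi_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)[!object$excluded, ]
  best <- attr(object, "best_wavelength")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength, y = .data$median_abs_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Detector wavelength (nm)",
      y = "Median |error| (%)",
      title = sprintf("Single-wavelength calibration error (optimum %.1f nm)", best)
    )
}

#' Plot UVI-normalized spectra and their collapse point
#'
#' Erythema-weighted, UVI-normalized spectra overlaid (one line per spectrum)
#' with the per-wavelength coefficient of variation; the CV minimum is the
#' collapse point.
#'
#' @param object A `uvi_collapse` from [normalized_collapse()].
#' @param max_curves Plot at most this many individual spectra.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uvi_collapse
#' @export
autoplot.uvi_collapse <- function(object, max_curves = 200, ...) {
  ids <- unique(object$curves$id)
  if (length(ids) > max_curves) ids <- ids[seq_len(max_curves)]
  df <- object$curves[object$curves$id %in% ids, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength, y = .data$value,
                                   group = .data$id)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::geom_vline(xintercept = object$collapse_wavelength,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "Wavelength (nm)",
      y = expression("Weighted irradiance / UVI  (mW" * m^-2 * nm^-1 * "/UVI)"),
      title = sprintf("Normalized spectra collapse at %.1f nm",
                      object$collapse_wavelength)
    )
}

#' Plot an accuracy (tolerance ECDF) curve
#'
#' @param object A `uvi_accuracy` from [accuracy_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uvi_accuracy
#' @export
autoplot.uvi_accuracy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tolerance, y = .data$accuracy)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Tolerance t (%)", y = "Spectra within tolerance (%)")
}

#' Scatter projection of the engineering-accuracy map
#'
#' Projects the parameter-space accuracy map onto two chosen axes, colouring
#' each point by the engineering accuracy of the 310 nm rule.
#'
#' @param map Tibble from [engineering_accuracy_map()].
#' @param x,y Axis column names (any two of `"A"`, `"B"`, `"z_du"`).
#' @return A ggplot object.
#' @export
plot_error_map <- function(map, x = "A", y = "z_du") {
  stopifnot(all(c(x, y, "engineering_accuracy") %in% names(map)))
  ggplot2::ggplot(map, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                    colour = .data$engineering_accuracy)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "|77 I310/UVI - 1|") +
    ggplot2::labs(x = x, y = y)
}
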