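#' Construct a spectral irradiance table
#'
#' A spectrum is an ordinary tibble with a strictly increasing `wavelength`
#' column (nm) and a non-negative `irradiance` column (mW m^-2 nm^-1). All
#' functions in the package accept any data frame with these two columns;
#' `spectrum()` validates and, by default, cleans raw instrument data.
#'
#' Negative irradiance values (common instrument noise at the short-wavelength
#' end of Brewer spectra) are clipped to zero with a message reporting the
#' count; `negative = "error"` rejects them instead. Values are never silently
#' kept negative.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param irradiance Numeric vector of spectral irradiance in mW m^-2 nm^-1.
#' @param negative Policy for negative irradiance: `"clip"` (default, clip to
#'   zero and report the count) or `"error"`.
#' @param site,timestamp,sza_deg Optional metadata stored as attributes.
#' @return A tibble with columns `wavelength` and `irradiance`.
#' @examples
#' spectrum(seq(300, 320, 0.5), rep(25, 41))
#' @export
spectrum <- function(wavelength, irradiance, negative = c("clip", "error"),
                     site = NULL, timestamp = NULL, sza_deg = NULL) {
  negative <- match.arg(negative)
  wavelength <- as.numeric(wavelength)
  irradiance <- as.numeric(irradiance)
  if (length(wavelength) != length(irradiance)) {
    stop("`wavelength` and `irradiance` must have the same length.", call. = FALSE)
  }
  if (anyNA(wavelength) || anyNA(irradiance)) {
    stop("Spectra must not contain missing values.", call. = FALSE)
  }
  if (length(wavelength) >= 2 && any(diff(wavelength) <= 0)) {
    stop("`wavelength` must be strictly increasing.", call. = FALSE)
  }
  n_neg <- sum(irradiance < 0)
  if (n_neg > 0) {
    if (negative == "error") {
      stop(n_neg, " negative irradiance value(s); use negative = \"clip\" to clean.",
           call. = FALSE)
    }
    message("Clipped ", n_neg, " negative irradiance value(s) to zero.")
    irradiance[irradiance < 0] <- 0
  }
  out <- tibble::tibble(wavelength = wavelength, irradiance = irradiance)
  meta <- list(site = site, timestamp = timestamp, sza_deg = sza_deg)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta)) attr(out, "meta") <- meta
  out
}

#' Construct a spectral weighting curve
#'
#' A weight curve pairs a strictly increasing wavelength grid (nm) with
#' dimensionless non-negative weights. It represents either an action
#' spectrum (e.g. erythema) or a detector's spectral sensitivity.
#'
#' @param wavelength Numeric, nm, strictly increasing.
#' @param weight Numeric, dimensionless, non-negative.
#' @return A tibble with columns `wavelength` and `weight`.
#' @export
weight_curve <- function(wavelength, weight) {
  wavelength <- as.numeric(wavelength)
  weight <- as.numeric(weight)
  if (length(wavelength) != length(weight)) {
    stop("`wavelength` and `weight` must have the same length.", call. = FALSE)
  }
  if (length(wavelength) >= 2 && any(diff(wavelength) <= 0)) {
    stop("`wavelength` must be strictly increasing.", call. = FALSE)
  }
  if (anyNA(weight) || any(weight < 0)) {
    stop("Weights must be non-negative and non-missing.", call. = FALSE)
  }
  tibble::tibble(wavelength = wavelength, weight = weight)
}

# internal: validate a spectrum-shaped data frame, no cleaning
check_spectrum <- function(spec, min_points = 1L) {
  if (!is.data.frame(spec) || !all(c("wavelength", "irradiance") %in% names(spec))) {
    stop("Expected a data frame with `wavelength` and `irradiance` columns.",
         call. = FALSE)
  }
  if (nrow(spec) < min_points) {
    stop("Spectrum has ", nrow(spec), " point(s); at least ", min_points,
         " required.", call. = FALSE)
  }
  if (nrow(spec) >= 2 && any(diff(spec$wavelength) <= 0)) {
    stop("Spectrum wavelengths must be strictly increasing.", call. = FALSE)
  }
  if (any(spec$irradiance < 0)) {
    stop("Spectrum contains negative irradiance; construct it with spectrum() ",
         "to apply the declared clipping policy.", call. = FALSE)
  }
  invisible(spec)
}

# internal: trapezoid quadrature weights for an arbitrary increasing grid
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n < 2) stop("At least 2 grid points are required for integration.", call. = FALSE)
  d <- diff(x)
  c(d[1], d[-(n - 1)] + d[-1], d[n - 1]) / 2
}

#' Integrate the product of a spectrum and a weight curve
#'
#' Computes the trapezoid-rule integral of `irradiance(lambda) * weight(lambda)`
#' over the spectrum's native wavelength grid (mW m^-2). This models the output
#' current of a radiometer whose spectral sensitivity is `curve`, and is the
#' quadrature underlying [compute_uvi()].
#'
#' The weight curve is linearly interpolated onto the spectrum's grid; weights
#' are zero outside the curve's wavelength range. The two wavelength ranges
#' must overlap.
#'
#' @param spec Spectrum data frame (`wavelength` nm, `irradiance` mW m^-2 nm^-1).
#' @param curve Weight curve data frame (`wavelength` nm, `weight`
#'   dimensionless).
#' @return The integral, a single number in mW m^-2.
#' @examples
#' sp <- spectrum(seq(250, 400, 0.5), rep(25, 301))
#' integrate_product(sp, weight_curve(c(250, 400), c(1, 1))) # 25 * 150 = 3750
#' @export
integrate_product <- function(spec, curve) {
  check_spectrum(spec, min_points = 2L)
  if (!is.data.frame(curve) || !all(c("wavelength", "weight") %in% names(curve))) {
    stop("`curve` must have `wavelength` and `weight` columns.", call. = FALSE)
  }
  if (max(curve$wavelength) < min(spec$wavelength) ||
      min(curve$wavelength) > max(spec$wavelength)) {
    stop("Spectrum and weight curve wavelength ranges do not overlap.", call. = FALSE)
  }
  w <- interp_zero(curve$wavelength, curve$weight, spec$wavelength)
  sum(trapezoid_weights(spec$wavelength) * spec$irradiance * w)
}

# internal: linear interpolation, zero outside the source range
interp_zero <- function(x, y, xout) {
  if (length(x) == 1L) return(ifelse(xout == x, y, 0))
  stats::approx(x, y, xout = xout, method = "linear", yleft = 0, yright = 0)$y
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation within the source range; target wavelengths outside
#' the source range are set to zero with a warning (extrapolating smooth
#' spectral curves would invent energy).
#'
#' @param spec Spectrum data frame.
#' @param grid Strictly increasing numeric vector of target wavelengths (nm).
#'   Must overlap the source range.
#' @return A spectrum tibble on `grid`.
#' @export
resample_spectrum <- function(spec, grid) {
  check_spectrum(spec, min_points = 2L)
  grid <- as.numeric(grid)
  if (length(grid) >= 2 && any(diff(grid) <= 0)) {
    stop("Target `grid` must be strictly increasing.", call. = FALSE)
  }
  rng <- range(spec$wavelength)
  if (max(grid) < rng[1] || min(grid) > rng[2]) {
    stop("Target grid does not overlap the source wavelength range.", call. = FALSE)
  }
  outside <- grid < rng[1] | grid > rng[2]
  if (any(outside)) {
    warning(sum(outside), " target wavelength(s) outside the source range set to 0.",
            call. = FALSE)
  }
  tibble::tibble(
    wavelength = grid,
    irradiance = interp_zero(spec$wavelength, spec$irradiance, grid)
  )
}

#' Read a two-column spectral table from a plain-text file
#'
#' Parses whitespace- or comma-separated two-column numeric tables
#' (wavelength nm, value). Comment lines and an optional fixed-count header
#' block are skipped; published ozone cross-section tables, for example, carry
#' a 21-line preamble (`skip = 21`).
#'
#' @param path File path.
#' @param skip Number of leading lines to skip before the data body.
#' @param comment Comment prefix; lines starting with it are dropped.
#' @param delim Field delimiter; `NULL` (default) splits on commas and/or
#'   whitespace.
#' @param value_name Name for the second column: `"irradiance"` (default) or
#'   e.g. `"sigma"`, `"weight"`.
#' @param negative Negative-value policy passed to [spectrum()] when
#'   `value_name = "irradiance"`.
#' @return A tibble with `wavelength` and the named value column.
#' @export
read_spectrum_table <- function(path, skip = 0, comment = "#", delim = NULL,
                                value_name = "irradiance",
                                negative = c("clip", "error")) {
  lines <- readLines(path, warn = FALSE)
  line_no <- seq_along(lines)
  if (skip > 0) {
    keep <- line_no > skip
    lines <- lines[keep]
    line_no <- line_no[keep]
  }
  if (nzchar(comment)) {
    keep <- !startsWith(trimws(lines), comment)
    lines <- lines[keep]
    line_no <- line_no[keep]
  }
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- line_no[keep]
  if (!length(lines)) stop("No data rows found in ", path, call. = FALSE)

  split_re <- if (is.null(delim)) "[,[:space:]]+" else delim
  fields <- strsplit(trimws(lines), split_re)
  # a single non-numeric first row is tolerated as a column header
  first <- suppressWarnings(as.numeric(fields[[1]]))
  if (anyNA(first) && length(fields) > 1) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  parsed <- lapply(fields, function(f) suppressWarnings(as.numeric(f[1:2])))
  bad <- vapply(parsed, anyNA, logical(1)) |
    vapply(fields, function(f) length(f) < 2, logical(1))
  if (any(bad)) {
    stop("Non-numeric or short data row at line ", line_no[which(bad)[1]],
         " of ", path, call. = FALSE)
  }
  m <- do.call(rbind, parsed)
  if (nrow(m) >= 2 && any(diff(m[, 1]) <= 0)) {
    stop("Wavelengths in ", path, " are not strictly increasing.", call. = FALSE)
  }
  if (identical(value_name, "irradiance")) {
    spectrum(m[, 1], m[, 2], negative = negative)
  } else {
    out <- tibble::tibble(wavelength = m[, 1], value = m[, 2])
    names(out)[2] <- value_name
    out
  }
}

#' Write a spectrum (or any two-column spectral table) to CSV
#'
#' Values are printed with 17 significant digits so that a write/read
#' round trip reproduces them exactly. The header names the units.
#'
#' @param spec Data frame whose first two columns are wavelength and a value.
#' @param path Output file path.
#' @param value_unit Unit string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(spec, path, value_unit = "mW_m2_nm") {
  stopifnot(is.data.frame(spec), ncol(spec) >= 2)
  header <- paste0("wavelength_nm,", names(spec)[2], "_", value_unit)
  body <- sprintf("%.17g,%.17g", spec[[1]], spec[[2]])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Standard wavelength grids
#'
#' `brewer_grid()` is the 286-363 nm grid in 0.5 nm channels used by Brewer
#' spectrometers; `full_uv_grid()` covers the full 250-400 nm range of the
#' erythema action spectrum at the same spacing.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
brewer_grid <- function() seq(286, 363, by = 0.5)

#' @rdname brewer_grid
#' @export
full_uv_grid <- function() seq(250, 400, by = 0.5)
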