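#' Summarise fitted atmospheric parameters
#'
#' Per-axis mean and standard deviation of fitted (A, B, z) triples, ignoring
#' non-converged fits. Used to characterise the naturally occurring parameter
#' range before sampling a box around it with [sample_box()].
#'
#' @param fits Data frame with columns `A`, `B`, `z_du` and optionally
#'   `converged` (rows with `converged = FALSE` are dropped and counted).
#' @return A tibble with one row per parameter: `parameter`, `mean`, `sd`,
#'   `n`; attribute `n_dropped` counts non-converged fits.
#' @export
summarize_fits <- function(fits) {
  stopifnot(is.data.frame(fits))
  need <- c("A", "B", "z_du")
  if (!all(need %in% names(fits))) {
    stop("`fits` needs columns A, B, z_du.", call. = FALSE)
  }
  n_dropped <- 0L
  if ("converged" %in% names(fits)) {
    n_dropped <- sum(!fits$converged)
    fits <- fits[fits$converged, , drop = FALSE]
  }
  if (nrow(fits) == 0) stop("No converged fits.", call. = FALSE)
  if (nrow(fits) < 2) {
    stop("At least 2 converged fits are required (SD undefined for 1).",
         call. = FALSE)
  }
  out <- tibble::tibble(
    parameter = need,
    mean = unname(vapply(fits[need], mean, 0)),
    sd = unname(vapply(fits[need], stats::sd, 0)),
    n = nrow(fits)
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Sample an atmospheric parameter box
#'
#' Uniform samples over `[center - 2 sd, center + 2 sd]` on each of the three
#' model axes, clipped to the physical constraints `A >= 0` and `z >= 0`.
#' This covers the observed parameter range extended by two standard
#' deviations along each axis.
#'
#' @param center Named numeric (`A`, `B`, `z_du`): box center, typically the
#'   means from [summarize_fits()].
#' @param sd Named numeric (`A`, `B`, `z_du`): per-axis standard deviations
#'   (>= 0). `sd = 0` collapses that axis to the center.
#' @param n Number of samples.
#' @param seed Integer seed for reproducibility.
#' @return A tibble with columns `A`, `B`, `z_du`.
#' @export
sample_box <- function(center, sd, n, seed = 1L) {
  need <- c("A", "B", "z_du")
  if (!all(need %in% names(center)) || !all(need %in% names(sd))) {
    stop("`center` and `sd` need named entries A, B, z_du.", call. = FALSE)
  }
  center <- vapply(as.list(center[need]), as.numeric, 0)
  sd <- vapply(as.list(sd[need]), as.numeric, 0)
  if (any(is.na(center)) || any(is.na(sd)) || any(sd < 0)) {
    stop("Invalid center or sd.", call. = FALSE)
  }
  if (center["A"] < 0 || center["z_du"] < 0) {
    stop("Box center must satisfy A >= 0 and z_du >= 0.", call. = FALSE)
  }
  with_seed(as.integer(seed), {
    draw <- function(axis, lo_bound) {
      x <- stats::runif(n, center[axis] - 2 * sd[axis], center[axis] + 2 * sd[axis])
      pmax(x, lo_bound)
    }
    tibble::tibble(
      A = draw("A", 0),
      B = stats::runif(n, center["B"] - 2 * sd["B"], center["B"] + 2 * sd["B"]),
      z_du = draw("z_du", 0)
    )
  })
}

#' Map the engineering accuracy of the 310 nm rule over parameter space
#'
#' For each atmospheric parameter point: computes the full model spectrum on
#' a 250-400 nm grid, its UVI, the irradiance interpolated at exactly
#' 310.0 nm, and the engineering accuracy of the single-wavelength rule
#' `UVI = 77 I310` (I310 in W m^-2 nm^-1):
#' \deqn{e = |77\, I_{310} / UVI - 1|}
#' The gray-loss parameter A cancels exactly from `e`, which is why the rule
#' survives arbitrary cloud and aerosol attenuation; ozone column and zenith
#' angle are what move it.
#'
#' The UVI here uses the full 250-400 nm model range: the map characterises
#' the physical approximation, not an instrument's bandpass.
#'
#' @param points Data frame with columns `A`, `B`, `z_du` (e.g. from
#'   [sample_box()]) and optionally `phi_deg` per point.
#' @param refs Reference curves from [reference_curves()].
#' @param phi_deg Solar zenith angle (degrees) applied to points lacking a
#'   `phi_deg` column.
#' @param uvi_per_w Rule constant, UVI per (W m^-2 nm^-1).
#' @param grid Wavelength grid for the model spectra.
#' @return A tibble: `A`, `B`, `z_du`, `phi_deg`, `uvi`, `i310`
#'   (mW m^-2 nm^-1) and `engineering_accuracy`.
#' @export
engineering_accuracy_map <- function(points, refs = reference_curves(),
                                     phi_deg = 30, uvi_per_w = 77,
                                     grid = full_uv_grid()) {
  stopifnot(is.data.frame(points))
  need <- c("A", "B", "z_du")
  if (!all(need %in% names(points))) {
    stop("`points` needs columns A, B, z_du.", call. = FALSE)
  }
  phi <- if ("phi_deg" %in% names(points)) points$phi_deg else rep(phi_deg, nrow(points))
  if (any(phi < 0 | phi >= 90)) stop("phi_deg must be in [0, 90).", call. = FALSE)
  rc <- resolve_refs(refs, grid)
  m <- huber_matrix(points$A, points$B, points$z_du, phi, rc$solar, rc$sigma, grid)
  tw <- trapezoid_weights(grid)
  ery <- tw * erythema_weight(grid)
  uvi <- as.numeric(m %*% ery) / uvi_reference
  # linear interpolation of each spectrum at exactly 310.0 nm
  j <- findInterval(310, grid)
  i310 <- if (grid[j] == 310) {
    m[, j]
  } else {
    f <- (310 - grid[j]) / (grid[j + 1] - grid[j])
    (1 - f) * m[, j] + f * m[, j + 1]
  }
  tibble::tibble(
    A = points$A, B = points$B, z_du = points$z_du, phi_deg = phi,
    uvi = uvi, i310 = i310,
    engineering_accuracy = abs(uvi_per_w * (i310 / 1000) / uvi - 1)
  )
}
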