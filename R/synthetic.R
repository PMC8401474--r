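# Frozen constants of the built-in reference-curve approximations.
# Solar: blackbody shape at the solar effective temperature, scaled to the
# published AM0 magnitude at 310 nm. Ozone: Huggins-band exponential anchored
# at the 273 K literature cross-section at 310 nm with a decay scale matching
# the published 310->320 nm decade rate. See the methods vignette for the
# calibration notes and for what these smooth surrogates cannot represent
# (spectral fine structure at the 0.5 nm channel scale).
solar_temperature_k <- 5778
solar_i310_mw <- 689
sigma_310_cm2 <- 8.0e-20
sigma_decay_nm <- 6.3

# internal closed forms ------------------------------------------------------

planck_shape <- function(wavelength_nm, temp_k = solar_temperature_k) {
  l <- wavelength_nm * 1e-9
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kb <- 1.380649e-23
  1 / (l^5 * (exp(h * c0 / (l * kb * temp_k)) - 1))
}

synth_solar_value <- function(wavelength_nm) {
  solar_i310_mw * planck_shape(wavelength_nm) / planck_shape(310)
}

synth_sigma_value <- function(wavelength_nm) {
  sigma_310_cm2 * exp(-(wavelength_nm - 310) / sigma_decay_nm)
}

#' Built-in approximate AM0 solar spectrum
#'
#' A smooth blackbody-shaped extraterrestrial solar spectrum scaled to the
#' published AM0 magnitude at 310 nm (689 mW m^-2 nm^-1). It reproduces the
#' magnitude and slope of the solar UV but none of its Fraunhofer line
#' structure; load a measured AM0 table into [reference_curves()] when channel
#' -scale realism matters.
#'
#' @param grid Wavelength grid, nm (within 250-400 nm).
#' @return A spectrum tibble.
#' @export
synth_solar_spectrum <- function(grid = full_uv_grid()) {
  tibble::tibble(wavelength = grid, irradiance = synth_solar_value(grid))
}

#' Built-in approximate ozone absorption cross-section
#'
#' Exponential Huggins-band approximation
#' `sigma(lambda) = 8.0e-20 * exp(-(lambda - 310)/6.3)` cm^2/molecule,
#' anchored at the 273 K literature value at 310 nm. Positive and
#' monotonically decreasing; within about 20 % of measured 273 K values over
#' 300-320 nm but without the Huggins oscillation structure.
#'
#' @param grid Wavelength grid, nm.
#' @return A tibble with columns `wavelength` (nm) and `sigma` (cm^2/molecule).
#' @export
synth_ozone_cross_section <- function(grid = full_uv_grid()) {
  tibble::tibble(wavelength = grid, sigma = synth_sigma_value(grid))
}

#' Configuration for a synthetic spectral ensemble
#'
#' Defines the atmospheric parameter distributions, measurement grid and
#' noise model used by [sample_params()] and [generate_ensemble()]. Defaults
#' emulate a multi-year Brewer record: ozone columns uniform over the
#' naturally occurring 250-500 DU range, gray losses spanning clear to heavily
#' overcast skies, mild spectral tilt, solar zenith angles from overhead to
#' low sun, and percent-level multiplicative measurement noise with a small
#' additive floor.
#'
#' @param n Number of spectra (>= 1).
#' @param grid Wavelength grid, nm; default the Brewer 286-363 nm, 0.5 nm grid.
#' @param a_range Gray aerosol/cloud loss bounds (dimensionless, >= 0).
#' @param b_range Spectral-tilt bounds, nm^-1.
#' @param z_range_du Ozone column bounds, Dobson Units.
#' @param phi_range_deg Solar zenith angle bounds, degrees, within `[0, 90)`.
#' @param noise_rel Relative standard deviation of multiplicative log-normal
#'   measurement noise (0 disables).
#' @param noise_floor Standard deviation of additive noise, mW m^-2 nm^-1
#'   (results are clipped at zero).
#' @param seed Integer seed; a fixed seed makes generation byte-identical.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n = 2000, grid = brewer_grid(),
                            a_range = c(0, 3),
                            b_range = c(-0.005, 0.005),
                            z_range_du = c(250, 500),
                            phi_range_deg = c(0, 70),
                            noise_rel = 0.02, noise_floor = 0.01,
                            seed = 1L) {
  stopifnot(length(grid) >= 2, all(diff(grid) > 0))
  if (n < 1) stop("`n` must be at least 1.", call. = FALSE)
  check_range <- function(r, name, lo = -Inf, hi = Inf) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      stop("Invalid bounds for ", name, ".", call. = FALSE)
    }
  }
  check_range(a_range, "a_range", lo = 0)
  check_range(b_range, "b_range")
  check_range(z_range_du, "z_range_du", lo = 0)
  check_range(phi_range_deg, "phi_range_deg", lo = 0, hi = 90 - 1e-9)
  if (noise_rel < 0 || noise_floor < 0) {
    stop("Noise parameters must be non-negative.", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), grid = grid, a_range = a_range, b_range = b_range,
         z_range_du = z_range_du, phi_range_deg = phi_range_deg,
         noise_rel = noise_rel, noise_floor = noise_floor,
         seed = as.integer(seed)),
    class = "ensemble_config"
  )
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat("Synthetic ensemble configuration\n")
  cat(sprintf("  n = %d spectra on %.1f-%.1f nm (%d channels)\n",
              x$n, min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("  A ~ U(%g, %g), B ~ U(%g, %g) nm^-1, z ~ U(%g, %g) DU, phi ~ U(%g, %g) deg\n",
              x$a_range[1], x$a_range[2], x$b_range[1], x$b_range[2],
              x$z_range_du[1], x$z_range_du[2],
              x$phi_range_deg[1], x$phi_range_deg[2]))
  cat(sprintf("  noise: %.3g relative (log-normal) + %.3g mW/m^2/nm additive; seed %d\n",
              x$noise_rel, x$noise_floor, x$seed))
  invisible(x)
}

# internal: run code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Draw atmospheric parameter sets from an ensemble configuration
#'
#' Seeded, reproducible uniform draws of (A, B, z, phi) over the bounds in the
#' configuration.
#'
#' @param config An [ensemble_config()] object.
#' @return A tibble with columns `id`, `A`, `B`, `z_du`, `phi_deg`.
#' @export
sample_params <- function(config) {
  stopifnot(inherits(config, "ensemble_config"))
  with_seed(config$seed, {
    n <- config$n
    tibble::tibble(
      id = seq_len(n),
      A = stats::runif(n, config$a_range[1], config$a_range[2]),
      B = stats::runif(n, config$b_range[1], config$b_range[2]),
      z_du = stats::runif(n, config$z_range_du[1], config$z_range_du[2]),
      phi_deg = stats::runif(n, config$phi_range_deg[1], config$phi_range_deg[2])
    )
  })
}

#' Generate a synthetic ensemble of Brewer-grid spectra
#'
#' Draws atmospheric parameters, computes each noise-free spectrum with the
#' single-layer forward model, applies multiplicative log-normal and additive
#' floor noise (clipped at zero), and records both the noise-free ("true")
#' UVI and the UVI computed from the noisy spectrum.
#'
#' @param config An [ensemble_config()] object.
#' @param refs Reference curves from [reference_curves()].
#' @return A tibble with one row per spectrum: the generating parameters,
#'   `uvi_true` (noise-free), `uvi` (from the noisy spectrum) and a `spectrum`
#'   list-column of spectrum tibbles. The wavelength grid is attached as
#'   attribute `grid`.
#' @examples
#' ens <- generate_ensemble(ensemble_config(n = 5, seed = 42))
#' ens$uvi
#' @export
generate_ensemble <- function(config, refs = reference_curves()) {
  stopifnot(inherits(config, "ensemble_config"))
  params <- sample_params(config)
  grid <- config$grid
  rc <- resolve_refs(refs, grid)
  clean <- huber_matrix(params$A, params$B, params$z_du, params$phi_deg,
                        rc$solar, rc$sigma, grid)
  noisy <- with_seed(config$seed + 1L, {
    m <- clean
    if (config$noise_rel > 0) {
      m <- m * exp(matrix(stats::rnorm(length(m), 0, config$noise_rel),
                          nrow(m), ncol(m)))
    }
    if (config$noise_floor > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, config$noise_floor),
                      nrow(m), ncol(m))
    }
    m[m < 0] <- 0
    m
  })
  tw <- trapezoid_weights(grid)
  ery <- tw * erythema_weight(grid)
  out <- params
  out$uvi_true <- as.numeric(clean %*% ery) / uvi_reference
  out$uvi <- as.numeric(noisy %*% ery) / uvi_reference
  out$spectrum <- lapply(seq_len(nrow(noisy)), function(i) {
    tibble::tibble(wavelength = grid, irradiance = noisy[i, ])
  })
  attr(out, "grid") <- grid
  out
}

# internal: irradiance matrix (n spectra x p channels) from an ensemble tibble,
# verifying that all spectra share one grid
ensemble_matrix <- function(ensemble) {
  if (!is.data.frame(ensemble) || !"spectrum" %in% names(ensemble)) {
    stop("Expected an ensemble tibble with a `spectrum` list-column.", call. = FALSE)
  }
  grids <- lapply(ensemble$spectrum, `[[`, "wavelength")
  g1 <- grids[[1]]
  same <- vapply(grids, function(g) length(g) == length(g1) && all(g == g1),
                 logical(1))
  if (!all(same)) stop("All spectra in an ensemble must share one grid.", call. = FALSE)
  list(grid = g1,
       irradiance = do.call(rbind, lapply(ensemble$spectrum, `[[`, "irradiance")))
}

#' Write or read an ensemble as a directory of spectral tables
#'
#' `write_ensemble()` writes one CSV per spectrum plus a `manifest.csv`
#' recording the generating parameters and true UVI; `read_ensemble()` loads
#' such a directory back into an ensemble tibble.
#'
#' @param ensemble An ensemble tibble from [generate_ensemble()].
#' @param dir Directory path.
#' @return `write_ensemble()` returns `dir` invisibly; `read_ensemble()`
#'   returns an ensemble tibble.
#' @export
write_ensemble <- function(ensemble, dir) {
  me <- ensemble_matrix(ensemble)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("spectrum_%05d.csv", ensemble$id)
  for (i in seq_len(nrow(ensemble))) {
    write_spectrum_table(ensemble$spectrum[[i]], file.path(dir, files[i]))
  }
  manifest <- dplyr::select(ensemble, -"spectrum")
  manifest$file <- files
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  specs <- lapply(manifest$file, function(f) {
    read_spectrum_table(file.path(dir, f))
  })
  out <- tibble::as_tibble(manifest[setdiff(names(manifest), "file")])
  out$spectrum <- specs
  attr(out, "grid") <- specs[[1]]$wavelength
  out
}
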