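# internal: small stable checksum of a configuration for output provenance
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}

# internal: write a tibble as CSV with a provenance/units comment header
write_stage_csv <- function(x, path, stage, units, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# uvindex %s", stage),
    sprintf("# units: %s", units),
    sprintf("# config: %s", hash)
  ), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic ensemble and write it to disk
#'
#' Wraps [generate_ensemble()] and [write_ensemble()]: one CSV per spectrum
#' plus a manifest recording the generating parameters, true UVI and seed.
#' Identical configurations (including seed) produce identical output.
#'
#' @param config An [ensemble_config()] object.
#' @param dir Output directory.
#' @param refs Reference curves from [reference_curves()].
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(config, dir, refs = reference_curves()) {
  stopifnot(inherits(config, "ensemble_config"))
  ens <- generate_ensemble(config, refs)
  write_ensemble(ens, dir)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  manifest$seed <- config$seed
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(tibble::as_tibble(manifest))
}

#' Run the full analysis pipeline on an ensemble
#'
#' Composes the analysis stages end to end: the per-wavelength calibration
#' scan, the detector comparison table, per-spectrum atmospheric-model fits
#' with their summary, and the engineering-accuracy map of the 310 nm rule
#' sampled over a box extending two standard deviations around the fitted
#' parameter means. All stage outputs are written as CSV (with units and a
#' configuration checksum in comment headers) and returned.
#'
#' @param ensemble An ensemble tibble (from [generate_ensemble()] /
#'   [read_ensemble()]) or a directory path written by [run_simulate()].
#' @param out_dir Output directory for stage CSVs.
#' @param refs Reference curves from [reference_curves()].
#' @param detectors Optional named list of detector sensitivity curves for
#'   [evaluate_detectors()].
#' @param fit Fit the atmospheric model to each spectrum (the slowest stage);
#'   set `FALSE` to skip fits and the map.
#' @param n_fit Maximum number of spectra to fit (first `n_fit` rows).
#' @param map_n Number of parameter-box samples for the accuracy map.
#' @param tolerance Accuracy tolerance, percent.
#' @param seed Seed for the map sampling.
#' @return A list with elements `scan`, `best_wavelength`, `detectors`,
#'   `fits`, `fit_summary`, `map` and `report` (one-row tibble of headline
#'   quantities: best wavelength and the 310 nm slope, intercept and R^2).
#' @export
run_analyze <- function(ensemble, out_dir, refs = reference_curves(),
                        detectors = NULL, fit = TRUE, n_fit = 500,
                        map_n = 500, tolerance = 10, seed = 1L) {
  if (is.character(ensemble)) ensemble <- read_ensemble(ensemble)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(list(n = nrow(ensemble), tolerance = tolerance,
                           n_fit = n_fit, map_n = map_n, seed = seed))

  scan <- scan_wavelengths(ensemble, tolerance = tolerance)
  write_stage_csv(as.data.frame(scan), file.path(out_dir, "scan.csv"),
                  "wavelength scan",
                  "wavelength nm; slope UVI per mW m^-2 nm^-1; errors %", hash)

  det <- evaluate_detectors(ensemble, detectors = detectors, tolerance = tolerance)
  write_stage_csv(det, file.path(out_dir, "detectors.csv"),
                  "detector comparison",
                  "signal mW m^-2; error %; accuracy %", hash)

  fits <- NULL; fit_summary <- NULL; map <- NULL
  if (fit) {
    idx <- seq_len(min(n_fit, nrow(ensemble)))
    fits <- purrr::map(idx, function(i) {
      f <- fit_huber(ensemble$spectrum[[i]], refs,
                     phi_deg = ensemble$phi_deg[i])
      tibble::tibble(id = ensemble$id[i], A = f$A, B = f$B, z_du = f$z_du,
                     phi_deg = f$phi_deg, rms = f$rms, converged = f$converged)
    })
    fits <- dplyr::bind_rows(fits)
    write_stage_csv(fits, file.path(out_dir, "fits.csv"),
                    "atmospheric-model fits",
                    "A dimensionless; B nm^-1; z_du DU; rms mW m^-2 nm^-1", hash)
    fit_summary <- summarize_fits(fits)
    box <- sample_box(
      center = stats::setNames(fit_summary$mean, fit_summary$parameter),
      sd = stats::setNames(fit_summary$sd, fit_summary$parameter),
      n = map_n, seed = seed
    )
    map <- engineering_accuracy_map(box, refs,
                                    phi_deg = stats::median(ensemble$phi_deg))
    write_stage_csv(map, file.path(out_dir, "map.csv"),
                    "engineering-accuracy map",
                    "z_du DU; uvi dimensionless; i310 mW m^-2 nm^-1; e dimensionless",
                    hash)
  }

  at310 <- which(scan$wavelength == 310)
  report <- tibble::tibble(
    n_spectra = nrow(ensemble),
    best_wavelength = best_wavelength(scan),
    slope_310 = if (length(at310)) scan$slope[at310] else NA_real_,
    intercept_310 = if (length(at310)) scan$intercept[at310] else NA_real_,
    r_squared_310 = if (length(at310)) scan$r_squared[at310] else NA_real_
  )
  write_stage_csv(report, file.path(out_dir, "report.csv"),
                  "summary report",
                  "wavelength nm; slope UVI per mW m^-2 nm^-1", hash)

  list(scan = scan, best_wavelength = best_wavelength(scan), detectors = det,
       fits = fits, fit_summary = fit_summary, map = map, report = report)
}
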