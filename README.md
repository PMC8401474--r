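# uvindex

Tools for erythemal UV dosimetry and UV-radiometer design: computing the UV
Index (UVI) from spectral irradiance, simulating and calibrating detector
designs, locating the single wavelength whose irradiance best predicts the
UVI, and exploring when that single-wavelength shortcut breaks down using a
single-layer atmospheric transmission model.

## The problem

The UVI is the erythemally weighted irradiance integral, scaled by a 25
mW m⁻² reference:

```
UVI = (1/25) ∫ w(λ) I(λ) dλ        [I in mW m⁻² nm⁻¹, λ in nm]
```

where *w(λ)* is the ISO/CIE 17166:2019 erythema action spectrum (1 up to
298 nm, then a steep log-linear decay). Building an affordable sensor that
reads the UVI is hard because consumer photodiodes do not match *w(λ)*, and
the solar UV spectrum changes shape with ozone column, solar elevation,
clouds and aerosols. Remarkably, the irradiance in a single narrow channel
near 310 nm tracks the UVI across all of that variation: a linearly
calibrated 310 nm detector is accurate where broad-band UV detectors fail.
This package implements the full analysis behind that claim as reusable,
tested building blocks for people designing or evaluating UV sensors.

## What is inside

* **Spectral core** — spectra and weighting curves as plain tibbles,
  trapezoid integration, resampling, robust two-column table I/O
  (`spectrum()`, `integrate_product()`, `read_spectrum_table()`).
* **Erythema/UVI** — the CIE action spectrum and the UVI integral
  (`erythema_weight()`, `compute_uvi()`, `erythemal_irradiance()`).
* **Atmospheric model** — a three-parameter single-layer transmission model
  `I(λ) = exp[−A + B(λ−320) − z σ(λ)/cos φ] · I_solar(λ)` with gray loss *A*,
  spectral tilt *B* (nm⁻¹), ozone column *z* and slant-path correction;
  forward simulation, Dobson-unit conversions, and per-spectrum fitting by
  Levenberg–Marquardt with an exact log-linear initializer
  (`huber_forward()`, `fit_huber()`, `loglinear_fit()`,
  `dobson_from_column()`).
* **Synthetic ensembles** — seeded Brewer-grid (286–363 nm, 0.5 nm channels)
  spectral ensembles over realistic parameter ranges with percent-level
  measurement noise, plus built-in smooth reference curves
  (`ensemble_config()`, `generate_ensemble()`, `synth_solar_spectrum()`,
  `synth_ozone_cross_section()`).
* **Detector calibration** — simulated detector currents, linear calibration
  `U = C₀ + C₁ M`, signed percent error and the accuracy-vs-tolerance ECDF,
  and a detector comparison table (`detector_current()`,
  `fit_calibration()`, `accuracy_curve()`, `evaluate_detectors()`).
* **Wavelength scan & collapse** — per-channel single-wavelength calibration
  scan and the UVI-normalized spectral collapse that both locate the optimum
  near 310 nm (`scan_wavelengths()`, `normalized_collapse()`).
* **Parameter-space map** — engineering accuracy `|77·I₃₁₀/UVI − 1|` of the
  single-wavelength rule over the (A, B, z) box two standard deviations
  around fitted conditions (`summarize_fits()`, `sample_box()`,
  `engineering_accuracy_map()`, `crossover_ozone()`).
* **Pipeline** — `run_simulate()` / `run_analyze()` write every stage as CSV
  with units and a config checksum; `autoplot()` methods draw the standard
  figures.

## Worked example

```r
library(uvindex)

# one model spectrum: moderate haze, 300 DU of ozone, sun 30 degrees off zenith
sp <- huber_forward(list(A = 1, B = 0.002, z_du = 300, phi_deg = 30))
compute_uvi(sp)
#> [1] 6.429

# recover the atmospheric parameters from the spectrum
tidy(fit_huber(sp, phi_deg = 30))
#> # A tibble: 3 × 3
#>   term   estimate unit
#>   <chr>     <dbl> <chr>
#> 1 A       1       dimensionless
#> 2 B       0.00200 nm^-1
#> 3 z_du  300       DU

# a synthetic multi-condition ensemble, and the single-wavelength scan
ens  <- generate_ensemble(ensemble_config(n = 500, seed = 42))
scan <- scan_wavelengths(ens)
best_wavelength(scan)
#> [1] 309.5
```

The scan's error curve is the headline result: channels dominated by ozone
absorption (300 nm) or by UV-A (350 nm) calibrate poorly, while a narrow
band near 310 nm predicts the UVI to a few percent:

```r
scan[scan$wavelength %in% c(300, 310, 350),
     c("wavelength", "median_abs_error", "accuracy")]
#>   wavelength median_abs_error accuracy
#> 1        300            49.5      10.2
#> 2        310             7.12     65.2
#> 3        350            29.2      20.2

evaluate_detectors(ens)
#>   detector     median_signal_rel_eas median_abs_error_pct accuracy_pct
#> 1 eas                          1                    0            100
#> 2 310nm boxcar                 0.783                7.35          66.8
#> 3 broad band                 149.                  27.9           22.6
```

An erythema-matched detector is perfect by construction; the 310 nm boxcar
is accurate within 10 % for two-thirds of all sky conditions; a 300–400 nm
broad-band detector is not usable. `autoplot(scan)`,
`autoplot(normalized_collapse(ens))` and `plot_error_map()` draw the
corresponding figures.

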