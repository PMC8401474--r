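Package: uvindex
Title: UV Index Estimation from Single-Wavelength Irradiance and a
    Single-Layer Atmospheric Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for erythemal UV dosimetry: computes the UV Index (UVI)
    from spectral irradiance using the ISO/CIE erythema action spectrum,
    simulates radiometer output for arbitrary spectral sensitivities and fits
    linear calibration models with percent-error and accuracy (ECDF)
    diagnostics, scans single-wavelength detectors across the UV to locate
    the optimal calibration wavelength near 310 nm, and provides a
    single-layer atmospheric transmission model (gray aerosol loss, spectral
    tilt, ozone column with slant-path correction) for generating synthetic
    Brewer-grid spectral ensembles, fitting measured spectra, and mapping
    where the single-wavelength UVI approximation holds across atmospheric
    parameter space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
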