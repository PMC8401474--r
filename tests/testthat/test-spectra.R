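test_that("integrate_product matches constant-integrand and zero-weight cases", {
  sp <- flat_spectrum(25)
  expect_equal(integrate_product(sp, unit_curve()), 25 * 150)
  expect_equal(integrate_product(sp, weight_curve(c(250, 400), c(0, 0))), 0)
  # erythema-weighted flat spectrum vs the closed-form piecewise integral
  expect_equal(integrate_product(sp, erythema_action_spectrum()),
               25 * eas_integral_exact(), tolerance = 1e-3)
})

test_that("integrate_product is linear in the spectrum", {
  g <- seq(290, 360, 0.5)
  set.seed(7)
  i1 <- runif(length(g), 0, 100)
  i2 <- runif(length(g), 0, 100)
  curve <- erythema_action_spectrum(g)
  lhs <- integrate_product(spectrum(g, 2 * i1 + 3 * i2), curve)
  rhs <- 2 * integrate_product(spectrum(g, i1), curve) +
    3 * integrate_product(spectrum(g, i2), curve)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("trapezoid integration agrees with an independent quadrature and converges", {
  skip_if_not_installed("pracma")
  g <- seq(286, 363, 0.5)
  sp <- spectrum(g, 500 * exp(-(g - 320)^2 / 400))
  curve <- erythema_action_spectrum(g)
  ours <- integrate_product(sp, curve)
  oracle <- pracma::trapz(g, sp$irradiance * erythema_weight(g))
  expect_equal(ours, oracle, tolerance = 1e-12)
  # halving the grid spacing moves the flat-spectrum erythemal integral < 0.1 %
  coarse <- integrate_product(flat_spectrum(25, by = 0.5), erythema_action_spectrum())
  fine <- integrate_product(flat_spectrum(25, by = 0.25), erythema_action_spectrum())
  expect_lt(abs(fine / coarse - 1), 1e-3)
})

test_that("integrate_product rejects degenerate and non-overlapping inputs", {
  expect_error(integrate_product(spectrum(310, 5), unit_curve()), "at least 2")
  sp <- flat_spectrum(10, lo = 300, hi = 320)
  expect_error(integrate_product(sp, weight_curve(c(350, 360), c(1, 1))),
               "overlap")
})

test_that("spectrum constructor enforces invariants and the negative policy", {
  expect_error(spectrum(c(300, 300, 301), c(1, 1, 1)), "strictly increasing")
  expect_error(spectrum(c(301, 300), c(1, 1)), "strictly increasing")
  expect_message(sp <- spectrum(c(300, 301, 302), c(-1, 2, -0.5)), "Clipped 2")
  expect_equal(sp$irradiance, c(0, 2, 0))
  expect_error(spectrum(c(300, 301), c(-1, 2), negative = "error"), "negative")
})

test_that("resampling interpolates linearly and zeroes outside the range", {
  sp <- spectrum(c(300, 302), c(0, 10))
  expect_equal(resample_spectrum(sp, 301)$irradiance, 5)
  # identity grid
  sp2 <- flat_spectrum(25, 300, 320)
  expect_equal(resample_spectrum(sp2, sp2$wavelength), sp2)
  # constant stays constant on interior grids
  expect_equal(resample_spectrum(sp2, seq(305, 315, 0.3))$irradiance,
               rep(25, length(seq(305, 315, 0.3))))
  expect_warning(out <- resample_spectrum(sp2, c(295, 310, 325)), "outside")
  expect_equal(out$irradiance, c(0, 25, 0))
  expect_error(resample_spectrum(sp2, c(350, 360)), "overlap")
})

test_that("spectral tables round-trip losslessly and reject malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  g <- seq(286, 290, 0.5)
  sp <- spectrum(g, exp(seq(-3, 5, length.out = length(g))) * pi)
  write_spectrum_table(sp, path)
  back <- read_spectrum_table(path)
  expect_identical(back$wavelength, sp$wavelength)
  expect_identical(back$irradiance, sp$irradiance)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("310 5", "309 4"), bad)
  expect_error(read_spectrum_table(bad), "strictly increasing")

  bad2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("300 1", "301 two", "302 3"), bad2)
  expect_error(read_spectrum_table(bad2), "line 2")
})

test_that("header blocks are skipped with skip =", {
  path <- withr::local_tempfile(fileext = ".dat")
  header <- sprintf("preamble line %d with text", 1:21)
  writeLines(c(header, "300.0 1.5", "300.5 2.5"), path)
  out <- read_spectrum_table(path, skip = 21)
  expect_equal(out$wavelength, c(300, 300.5))
  expect_equal(out$irradiance, c(1.5, 2.5))
  # comma-delimited with comments and a column header row
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# a comment", "wavelength,value", "300,1", "301,2"), path2)
  out2 <- read_spectrum_table(path2)
  expect_equal(out2$irradiance, c(1, 2))
})
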