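test_that("detector currents reproduce hand-computed integrals", {
  sp <- flat_spectrum(25)
  expect_equal(detector_current(sp, builtin_sensitivity("boxcar", grid = sp$wavelength,
                                                        center = 310, width = 1)),
               25, tolerance = 1e-12)
  expect_equal(detector_current(sp, builtin_sensitivity("flatband", grid = sp$wavelength,
                                                        lo = 300, hi = 400)),
               2500, tolerance = 1e-12)
  # erythema-matched detector reads exactly 25 x UVI (same quadrature)
  model_sp <- huber_forward(list(A = 0.7, B = 0.001, z_du = 320, phi_deg = 35))
  eas <- builtin_sensitivity("eas", grid = model_sp$wavelength)
  expect_equal(detector_current(model_sp, eas),
               25 * as.numeric(compute_uvi(model_sp)), tolerance = 1e-14)
})

test_that("builtin sensitivities have the declared shapes", {
  g <- brewer_grid()
  box <- builtin_sensitivity("boxcar", grid = g, center = 310, width = 1)
  expect_equal(box$weight[g == 310], 1)
  expect_equal(box$weight[g %in% c(309.5, 310.5)], c(0.5, 0.5))
  expect_true(all(box$weight[abs(g - 310) > 0.5] == 0))
  flat <- builtin_sensitivity("flatband", grid = g, lo = 300, hi = 400)
  expect_true(all(flat$weight[g > 300] == 1))
  expect_equal(flat$weight[g == 300], 0.5)
  expect_true(all(flat$weight[g < 300] == 0))
  expect_equal(builtin_sensitivity("eas", grid = g)$weight,
               erythema_action_spectrum(g)$weight)
  # arbitrary measured curve from a two-column table
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("305,0", "310,1", "315,0"), path)
  tab <- builtin_sensitivity("from_table", grid = g, path = path)
  expect_equal(tab$weight[g == 310], 1)
  expect_equal(tab$weight[g == 307.5], 0.5)
  expect_equal(tab$weight[g == 330], 0)
  expect_error(builtin_sensitivity("nonsense"), "arg")
})

test_that("linear calibration recovers exact lines and flags singular designs", {
  m <- c(1, 2, 3, 4)
  cal <- fit_calibration(m, 2 * m + 1)
  expect_equal(cal$c1, 2, tolerance = 1e-12)
  expect_equal(cal$c0, 1, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  # two points always interpolate
  cal2 <- fit_calibration(c(1, 3), c(5, 9))
  expect_equal(predict(cal2, 2), 7, tolerance = 1e-12)
  expect_equal(cal2$r_squared, 1)
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "Constant")
  expect_error(fit_calibration(1, 1), "2 observations")
  td <- tidy(cal)
  expect_equal(td$estimate, c(1, 2), tolerance = 1e-12)
  expect_equal(glance(cal)$n, 4)
})

test_that("percent errors are signed and guard against non-positive UVI", {
  cal <- fit_calibration(c(0, 1), c(0, 1))  # identity
  expect_equal(percent_error(cal, 1.1, 1), 10, tolerance = 1e-9)
  expect_equal(percent_error(cal, 0.8, 1), -20, tolerance = 1e-9)
  expect_equal(percent_error(cal, 1, 1), 0, tolerance = 1e-9)
  expect_message(e <- percent_error(cal, c(1, 1), c(1, 0)), "Excluded 1")
  expect_true(is.na(e[2]))
})

test_that("accuracy curves are ECDFs of absolute error", {
  a <- accuracy_curve(c(-5, 5, 15), tolerances = c(0, 4, 10, 20))
  expect_equal(a$accuracy, c(0, 0, 100 * 2 / 3, 100))
  expect_true(all(diff(a$accuracy) >= 0))
  z <- accuracy_curve(rep(0, 10), tolerances = c(0, 1, 50))
  expect_equal(z$accuracy, c(100, 100, 100))
  set.seed(3)
  e <- rnorm(200, 0, 20)
  ac <- accuracy_curve(e, tolerances = seq(0, ceiling(max(abs(e))), 1))
  expect_true(all(diff(ac$accuracy) >= 0))
  expect_equal(ac$accuracy[length(ac$accuracy)], 100)
})

test_that("the erythema-matched detector is perfectly calibrated on any ensemble", {
  ens <- small_ensemble(n = 100)
  det <- evaluate_detectors(ens)
  eas_row <- det[det$detector == "eas", ]
  expect_lt(eas_row$median_abs_error_pct, 1e-8)
  expect_equal(eas_row$accuracy_pct, 100)
  expect_equal(eas_row$median_signal_rel_eas, 1, tolerance = 1e-12)
  expect_equal(eas_row$r_squared, 1, tolerance = 1e-10)
})

test_that("calibration absorbs sensitivity scale: errors invariant, signal doubled", {
  ens <- small_ensemble(n = 80)
  g <- attr(ens, "grid")
  box <- builtin_sensitivity("boxcar", grid = g, center = 310, width = 1)
  box2 <- weight_curve(box$wavelength, 2 * box$weight)
  det <- evaluate_detectors(ens, detectors = list(one = box, two = box2))
  expect_equal(det$median_abs_error_pct[1], det$median_abs_error_pct[2],
               tolerance = 1e-9)
  expect_equal(det$accuracy_pct[1], det$accuracy_pct[2])
  expect_equal(det$median_signal[2], 2 * det$median_signal[1], tolerance = 1e-12)
  # single-detector input gives a one-row table
  one <- evaluate_detectors(ens, detectors = list(solo = box))
  expect_equal(nrow(one), 1)
})
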