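test_that("Dobson conversions are first-principles consistent and exact inverses", {
  # 0.001 cm of ozone at STP, N_A molecules per 22.4 L
  expect_equal(dobson_from_column(2.6885e16), 1, tolerance = 1e-3)
  z <- c(0, 1e17, 8.07e18)
  expect_equal(column_from_dobson(dobson_from_column(z)), z, tolerance = 1e-15)
  expect_equal(dobson_from_column(0), 0)
  expect_error(dobson_from_column(-1), "non-negative")
  expect_error(column_from_dobson(-5), "non-negative")
})

test_that("forward model reduces to the solar spectrum under zero attenuation", {
  g <- brewer_grid()
  clear <- huber_forward(list(A = 0, B = 0, z_du = 0, phi_deg = 0), grid = g)
  expect_equal(clear$irradiance, synth_solar_spectrum(g)$irradiance,
               tolerance = 1e-14)
  gray <- huber_forward(list(A = log(2), B = 0, z_du = 0, phi_deg = 0), grid = g)
  expect_equal(gray$irradiance, clear$irradiance / 2, tolerance = 1e-12)
})

test_that("ozone attenuation at a single wavelength follows Beer's law", {
  g <- seq(300, 320, 0.5)
  sigma310 <- synth_ozone_cross_section(310)$sigma
  z_du <- dobson_from_column(1 / sigma310)  # unit optical depth at 310 nm
  sp <- huber_forward(list(A = 0, B = 0, z_du = z_du, phi_deg = 0), grid = g)
  expect_equal(sp$irradiance[g == 310],
               exp(-1) * synth_solar_spectrum(310)$irradiance,
               tolerance = 1e-10)
})

test_that("invalid model parameters are rejected", {
  expect_error(huber_forward(list(A = -1, B = 0, z_du = 300, phi_deg = 30)), "A must")
  expect_error(huber_forward(list(A = 0, B = 0, z_du = -3, phi_deg = 30)), "z_du")
  expect_error(huber_forward(list(A = 0, B = 0, z_du = 300, phi_deg = 90)), "zenith")
})

test_that("noiseless spectra are recovered exactly by both estimators", {
  truth <- list(A = 1, B = 0.002, z_du = 300, phi_deg = 30)
  sp <- huber_forward(truth)
  nl <- fit_huber(sp, phi_deg = 30)
  ll <- loglinear_fit(sp, phi_deg = 30)
  for (f in list(nl, ll)) {
    expect_lt(abs(f$A / truth$A - 1), 1e-6)
    expect_lt(abs(f$B / truth$B - 1), 1e-6)
    expect_lt(abs(f$z_du / truth$z_du - 1), 1e-6)
    expect_true(f$converged)
  }
  # nonlinear fit agrees with the log-linear oracle
  expect_lt(abs(nl$z_du / ll$z_du - 1), 1e-6)
  # identity spectrum: all parameters near zero
  id <- fit_huber(synth_solar_spectrum(brewer_grid()), phi_deg = 25)
  expect_lt(abs(id$A), 1e-8)
  expect_lt(abs(id$B), 1e-8)
  expect_lt(abs(id$z_du), 1e-4)
})

test_that("tidy and glance expose fit parameters and diagnostics", {
  f <- fit_huber(huber_forward(list(A = 0.5, B = 0, z_du = 280, phi_deg = 10)),
                 phi_deg = 10)
  td <- tidy(f)
  expect_equal(td$term, c("A", "B", "z_du"))
  expect_equal(td$estimate[3], 280, tolerance = 1e-6)
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$n_channels, length(brewer_grid()))
})

test_that("ozone column is recovered to a few DU under measurement noise", {
  cfg <- ensemble_config(n = 25, seed = 77)
  ens <- generate_ensemble(cfg)
  dz <- purrr::map_dbl(seq_len(nrow(ens)), function(i) {
    f <- fit_huber(ens$spectrum[[i]], phi_deg = ens$phi_deg[i])
    f$z_du - ens$z_du[i]
  })
  expect_lt(median(abs(dz)), 5)
  # the paired estimators agree within their joint noise scatter
  dz_ll <- purrr::map_dbl(seq_len(10), function(i) {
    loglinear_fit(ens$spectrum[[i]], phi_deg = ens$phi_deg[i])$z_du -
      fit_huber(ens$spectrum[[i]], phi_deg = ens$phi_deg[i])$z_du
  })
  expect_lt(median(abs(dz_ll)), 10)
})

test_that("UVI to I310 ratio is exactly invariant under gray attenuation", {
  ratios <- purrr::map_dbl(c(0, 1, 3), function(a) {
    sp <- huber_forward(list(A = a, B = 0.002, z_du = 300, phi_deg = 30))
    as.numeric(compute_uvi(sp)) / sp$irradiance[sp$wavelength == 310]
  })
  expect_lt(max(abs(ratios / ratios[1] - 1)), 1e-10)
})

test_that("UVI decreases with ozone column and with solar zenith angle", {
  uvi_at <- function(z_du, phi_deg) {
    as.numeric(compute_uvi(huber_forward(
      list(A = 0.5, B = 0, z_du = z_du, phi_deg = phi_deg)
    )))
  }
  u_z <- purrr::map_dbl(seq(250, 500, by = 50), uvi_at, phi_deg = 30)
  expect_true(all(diff(u_z) < 0))
  u_phi <- purrr::map_dbl(seq(0, 80, by = 10), uvi_at, z_du = 300)
  expect_true(all(diff(u_phi) < 0))
})

test_that("the 310 nm rule underestimates the UVI at ozone-hole columns", {
  # ozone-hole conditions: the short erythemal wavelengths flood in and the
  # true UVI outgrows 77 * I310
  rule_ratio <- function(z_du) {
    sp <- huber_forward(list(A = 0, B = 0, z_du = z_du, phi_deg = 30),
                        grid = full_uv_grid())
    i310_w <- sp$irradiance[sp$wavelength == 310] / 1000
    as.numeric(compute_uvi(sp)) / (77 * i310_w)
  }
  expect_gt(rule_ratio(93), 1)
  expect_gt(rule_ratio(93), rule_ratio(150))
  # and the crossover column is reported as a function of (B, phi)
  zc <- crossover_ozone(phi_deg = 30, B = 0)
  expect_true(is.finite(zc))
  expect_gt(rule_ratio(zc - 20), 1)
  expect_lt(rule_ratio(zc + 20), 1)
})

test_that("user-supplied reference tables override the built-ins", {
  g <- brewer_grid()
  solar_tab <- synth_solar_spectrum(seq(280, 370, 0.25))
  sigma_tab <- synth_ozone_cross_section(seq(280, 370, 0.25))
  refs <- reference_curves(solar = solar_tab, sigma = sigma_tab)
  a <- huber_forward(list(A = 1, B = 0.001, z_du = 300, phi_deg = 20), refs, g)
  b <- huber_forward(list(A = 1, B = 0.001, z_du = 300, phi_deg = 20), grid = g)
  expect_equal(a$irradiance, b$irradiance, tolerance = 1e-10)
  expect_error(resolve_refs(refs, seq(250, 400, 0.5)), "cover")
  expect_error(reference_curves(sigma = data.frame(wavelength = g,
                                                   sigma = rev(sort(runif(length(g)))) * 0 + 1)),
               "decrease")
})
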