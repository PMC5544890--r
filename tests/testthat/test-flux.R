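test_that("slope-to-flux conversion matches the hand ideal-gas oracle", {
  spec <- chamber_spec()
  expect_equal(compute_flux(0, 1, 293.15, spec), 0)
  # 1000 ppm/day at 1 atm, 20 C in the default chamber: ~44.4 mmol m-2 d-1
  f <- compute_flux(1000, 1, 293.15, spec)
  expect_equal(f, flux_oracle(1000, 1, 293.15, 197.4, 0.1849),
               tolerance = 1e-12)
  expect_equal(f, 44.4, tolerance = 2e-3)
  # linear in slope and in volume; inverse in temperature
  expect_equal(compute_flux(2000, 1, 293.15, spec), 2 * f, tolerance = 1e-12)
  sp2 <- chamber_spec(volume_l = 2 * 197.4)
  expect_equal(compute_flux(1000, 1, 293.15, sp2), 2 * f, tolerance = 1e-12)
  expect_equal(compute_flux(1000, 1, 2 * 293.15, spec), f / 2,
               tolerance = 1e-12)
  expect_error(compute_flux(10, 1, -3, spec), "temperature")
})

test_that("flux_to_slope inverts compute_flux exactly", {
  spec <- chamber_spec()
  for (f in c(0.3, 1, 20, 87)) {
    sl <- flux_to_slope(f, 0.99, 288.15, spec)
    expect_equal(compute_flux(sl, 0.99, 288.15, spec), f, tolerance = 1e-12)
  }
})

test_that("unit conversion to mg CH4 per hour reproduces printed figures", {
  expect_equal(mmol_per_day_to_mg_per_hour(0), 0)
  expect_equal(signif(mmol_per_day_to_mg_per_hour(87), 2), 58)
  expect_equal(round(mmol_per_day_to_mg_per_hour(1), 1), 0.7)
})

test_that("biomass normalisation and allometric estimation behave", {
  expect_equal(flux_per_biomass(10, 100), 0.1)
  expect_equal(flux_per_biomass(7.3, 1), 7.3)
  expect_equal(flux_per_biomass(3 * 10, 3 * 100), flux_per_biomass(10, 100))
  expect_error(flux_per_biomass(10, 0), "biomass")

  expect_equal(estimate_biomass("P. australis", shoot_count = 0,
                                shoot_height_cm = 50,
                                allometry = c(a = 1, b = 2)), 0)
  expect_equal(estimate_biomass("P. australis", shoot_count = 10,
                                shoot_height_cm = 2,
                                allometry = c(a = 0, b = 1)), 20)
  # floored at zero for a pathological regression
  expect_equal(estimate_biomass("P. australis", shoot_count = 5,
                                shoot_height_cm = 1,
                                allometry = c(a = -10, b = 1)), 0)
  expect_error(estimate_biomass("P. australis", shoot_count = 5,
                                shoot_height_cm = 10),
               "configuration error")
  # sedge route: matched harvest value passes through
  expect_equal(estimate_biomass("C. rostrata", harvest_dw_gdw = 140), 140)
  # construction: synthetic allometry recovers the configured dry weight
  a <- 0.8; b <- 0.05; count <- 23; height <- 81
  expect_equal(estimate_biomass("P. australis", count, height,
                                allometry = c(a, b)),
               count * (a + b * height))
})

test_that("zero-noise enclosures round-trip the injected flux exactly", {
  spec <- chamber_spec()
  for (f in c(0.5, 2, 10, 45, 87)) {
    for (tc in c(5, 15, 25)) {
      g <- simulate_chamber_series(f, spec, temp_c = tc, pressure_atm = 0.99)
      cf <- chamber_flux(g$t_s, g$ch4_ppm, temp_c = tc, pressure_atm = 0.99,
                         spec = spec)
      expect_equal(cf$ch4_flux_mmol_m2_d, f, tolerance = 1e-9)
      expect_false(cf$ebullition)
    }
  }
  # linearity: doubling the injected flux doubles the fitted slope
  g1 <- simulate_chamber_series(10, spec, 15, 0.99)
  g2 <- simulate_chamber_series(20, spec, 15, 0.99)
  f1 <- select_best_window(enumerate_windows(g1$t_s, g1$ch4_ppm, spec))
  f2 <- select_best_window(enumerate_windows(g2$t_s, g2$ch4_ppm, spec))
  expect_equal(f2$slope_ppm_d, 2 * f1$slope_ppm_d, tolerance = 1e-9)
})

test_that("flux estimate is invariant to a constant concentration offset", {
  spec <- chamber_spec()
  set.seed(3)
  t <- seq(0, 300, 20)
  ppm <- 1.9 + 200 * t / 86400 + rnorm(length(t), 0, 0.02)
  a <- chamber_flux(t, ppm, temp_c = 15, pressure_atm = 1, spec = spec)
  b <- chamber_flux(t, ppm + 5, temp_c = 15, pressure_atm = 1, spec = spec)
  expect_equal(a$ch4_flux_mmol_m2_d, b$ch4_flux_mmol_m2_d, tolerance = 1e-12)
  expect_equal(a$window$start_s, b$window$start_s)
})

test_that("CO2 channel is fitted over the chosen CH4 window", {
  spec <- chamber_spec()
  g <- simulate_chamber_series(10, spec, 15, 0.99, nee_flux = -300)
  cf <- chamber_flux(g$t_s, g$ch4_ppm, g$co2_ppm, temp_c = 15,
                     pressure_atm = 0.99, spec = spec)
  expect_equal(cf$co2_flux_mmol_m2_d, -300, tolerance = 1e-9)
})

test_that("max-r2 selection bias is small at the default analyser noise", {
  # documented property: selection by best r2 inflates weak slopes; at the
  # default 0.02 ppm noise and a mid-range flux the mean error stays small
  spec <- chamber_spec()
  set.seed(42)
  rec <- replicate(200, {
    g <- simulate_chamber_series(20, spec, 15, 0.99, noise_sd_ppm = 0.02)
    chamber_flux(g$t_s, g$ch4_ppm, temp_c = 15, pressure_atm = 0.99,
                 spec = spec)$ch4_flux_mmol_m2_d
  })
  expect_lt(abs(mean(rec) / 20 - 1), 0.02)
  # and the bias is genuinely positive and large at poor signal-to-noise
  set.seed(43)
  lo <- replicate(200, {
    g <- simulate_chamber_series(5, spec, 15, 0.99, noise_sd_ppm = 0.05)
    chamber_flux(g$t_s, g$ch4_ppm, temp_c = 15, pressure_atm = 0.99,
                 spec = spec)$ch4_flux_mmol_m2_d
  })
  expect_gt(mean(lo) / 5 - 1, 0.1)
})
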