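test_that("time-class assignment partitions the day into half-open bins", {
  expect_identical(assign_time_class(0), 0L)
  expect_identical(assign_time_class(23.983), 9L)          # 23:59
  expect_identical(assign_time_class(12), 5L)              # floor(12 / 2.4)
  expect_error(assign_time_class(24), "\\[0, 24\\)")
  expect_error(assign_time_class(-0.1), "\\[0, 24\\)")
  # every measurement maps to exactly one class; the 2-hourly schedule
  # fills all 10 classes with 1 or 2 values
  h12 <- seq(0, 22, by = 2)
  cls <- assign_time_class(h12)
  expect_true(all(cls %in% 0:9))
  expect_true(all(table(factor(cls, levels = 0:9)) %in% 1:2))
  h24 <- 0:23
  expect_true(all(table(assign_time_class(h24)) %in% 2:3))
})

test_that("class means equal a group-by oracle and flag empty classes", {
  h <- seq(0, 22, by = 2)
  v <- seq_along(h)
  m <- class_means(h, v)
  agg <- tapply(v, floor(h / 2.4), mean)
  expect_equal(unname(m[as.integer(names(agg)) + 1]), as.vector(agg))
  expect_equal(class_means(c(1, 13), c(4, 4)),
               {x <- rep(NA_real_, 10); x[c(1, 6)] <- 4; x})
  # constant flux: every non-empty class mean is that constant
  expect_true(all(class_means(h, rep(2.5, 12)) == 2.5))
  # random fill against the oracle
  set.seed(31)
  for (i in 1:20) {
    hh <- runif(30, 0, 24 - 1e-9)
    vv <- rnorm(30)
    m <- class_means(hh, vv)
    o <- tapply(vv, assign_time_class(hh), mean)
    expect_equal(unname(m[as.integer(names(o)) + 1]), as.vector(o))
  }
})

test_that("ICC reaches 1 for identical series and ~0 for unrelated ones", {
  # every daily series has the same (varying) diel profile: perfect agreement
  profile <- c(1, 3, 7, 2, 5, 9, 4, 6, 8, 2)
  mat <- matrix(profile, nrow = 6, ncol = 10, byrow = TRUE)
  r <- icc_agreement(mat)
  expect_equal(r$coefficient, 1, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-10)
  # unrelated i.i.d. series: mean coefficient near zero
  set.seed(71)
  v <- replicate(1000, icc_agreement(matrix(rnorm(250), 25, 10))$icc_single)
  expect_lt(abs(mean(v)), 0.05)
  expect_true(all(v <= 1))
  expect_error(icc_agreement(matrix(1, 4, 4)), "degenerate")
})

test_that("ICC matches an aov-decomposition oracle on a worked 4x3 matrix", {
  mat <- matrix(c(9, 2, 5,
                  6, 1, 7,
                  8, 4, 6,
                  7, 1, 2), nrow = 4, byrow = TRUE)
  r <- icc_agreement(mat)
  o <- icc_oracle(mat)
  expect_equal(r$icc_single, o$single, tolerance = 1e-8)
  expect_equal(r$icc_average, o$average, tolerance = 1e-8)
  # and on random matrices
  set.seed(17)
  for (i in 1:20) {
    m <- matrix(rnorm(60, sd = 2), nrow = 5)
    r <- icc_agreement(m)
    o <- icc_oracle(m)
    expect_equal(r$icc_single, o$single, tolerance = 1e-8)
    expect_equal(r$icc_average, o$average, tolerance = 1e-8)
  }
})

test_that("ICC is invariant to shifting and positive scaling of all cells", {
  set.seed(19)
  m <- matrix(rnorm(80), 8, 10)
  base <- icc_agreement(m)$icc_single
  expect_equal(icc_agreement(m + 100)$icc_single, base, tolerance = 1e-10)
  expect_equal(icc_agreement(m * 7)$icc_single, base, tolerance = 1e-10)
})

test_that("diel_icc assembles series, drops incomplete classes with warning", {
  set.seed(23)
  grid <- expand.grid(clock_hours = seq(0, 22, 2),
                      date = as.Date("2014-07-01") + c(0, 30, 60))
  fx <- data.frame(lake = "Erssjon", species = "P. australis",
                   date = grid$date, clock_hours = grid$clock_hours,
                   ch4_flux_mmol_m2_d = rnorm(nrow(grid), 10),
                   ebullition = FALSE)
  r <- diel_icc(fx)
  expect_s3_class(r, "icc_result")
  expect_identical(r$n_series, 3L)
  expect_identical(r$k_classes, 10L)
  # removing one series' sole class-1 measurement (04:00) empties that class
  fx2 <- fx[!(fx$date == fx$date[1] & fx$clock_hours == 4), ]
  expect_warning(r2 <- diel_icc(fx2), "dropping 1 time class")
  expect_identical(r2$k_classes, 9L)
})

test_that("a built-in diel cycle raises the ICC above the no-cycle case", {
  # power check: 50% flux modulation vs none, temperature cycle silenced
  wins <- logical(15)
  for (i in seq_along(wins)) {
    cfg_on <- small_config(seed = 400 + i, diel_flux_amplitude = 0.5,
                           diel_temp_amplitude = 0, ebullition_prob = 0)
    cfg_off <- small_config(seed = 400 + i, diel_temp_amplitude = 0,
                            ebullition_prob = 0)
    icc_on <- diel_icc(estimate_fluxes(simulate_chamber_study(cfg_on)))
    icc_off <- diel_icc(estimate_fluxes(simulate_chamber_study(cfg_off)))
    wins[i] <- icc_on$icc_single > icc_off$icc_single
  }
  expect_true(all(wins))
})

test_that("daily summaries use t-based intervals and handle singletons", {
  one <- daily_summary(4.2)
  expect_equal(one$mean, 4.2)
  expect_true(is.na(one$ci_half_width))
  pair <- daily_summary(c(2, 8))
  expect_equal(pair$mean, 5)
  set.seed(37)
  x <- rnorm(9, 10, 3)
  ds <- daily_summary(x)
  expect_equal(ds$ci_half_width, qt(0.975, 8) * sd(x) / 3,
               tolerance = 1e-12)
})

test_that("daily regression matches the textbook normal equations", {
  x <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(fit_daily_regression(x, 2 * x + 1))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$adj_r_squared, 1, tolerance = 1e-10)
  set.seed(41)
  xx <- rnorm(12); yy <- 3 - 0.5 * xx + rnorm(12, 0, 0.4)
  r <- fit_daily_regression(xx, yy)
  X <- cbind(1, xx)
  beta <- solve(t(X) %*% X, t(X) %*% yy)
  expect_equal(r$slope, beta[2], tolerance = 1e-10)
  expect_equal(r$intercept, beta[1], tolerance = 1e-10)
  expect_error(fit_daily_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_daily_regression(rep(1, 5), 1:5), "zero variance")
})

test_that("slope p-values are calibrated under the null", {
  set.seed(43)
  n_rep <- 1000
  p <- replicate(n_rep, {
    fit_daily_regression(rnorm(13), rnorm(13))$p_value
  })
  rej <- mean(p < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})
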