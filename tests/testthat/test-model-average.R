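test_that("thinning keeps every second value of full hourly days only", {
  x <- 1:24
  expect_equal(thin_series(x), seq(1, 23, 2))
  expect_length(thin_series(x), 12L)
  expect_identical(thin_series(1:12), 1:12)
  expect_identical(thin_series(1:23), 1:23)      # rule applies only to 24
  df <- data.frame(clock_hours = 0:23, v = 101:124,
                   lake = "Erssjon", species = "P. australis",
                   date = as.Date("2014-06-09"))
  th <- thin_by_day(df)
  expect_equal(th$v, seq(101, 123, 2))
})

test_that("standardization yields mean 0 and SD 0.5 with the sample SD", {
  set.seed(51)
  for (x in list(rnorm(40, 10, 3), runif(15), c(0, 1))) {
    z <- standardize_half_sd(x)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 0.5, tolerance = 1e-12)
  }
  # two-point hand check: (x - 0.5) / (2 * sd(c(0, 1)))
  z <- standardize_half_sd(c(0, 1))
  expect_equal(as.numeric(z), (c(0, 1) - 0.5) / (2 * sd(c(0, 1))),
               tolerance = 1e-12)
  # idempotent up to the same contract
  z2 <- standardize_half_sd(as.numeric(z))
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 0.5, tolerance = 1e-12)
  expect_error(standardize_half_sd(rep(3, 5)), "zero variance")
})

test_that("collinearity screen drops coupled pairs and reports VIFs", {
  set.seed(53)
  n <- 200
  a <- rnorm(n); b <- rnorm(n); c <- rnorm(n)
  # orthogonal-ish predictors: all VIFs near 1
  sc <- collinearity_screen(data.frame(a, b, c))
  expect_identical(sc$retained, c("a", "b", "c"))
  expect_true(all(abs(sc$vif - vif_oracle(data.frame(a, b, c))) < 1e-10))
  # a duplicated predictor is flagged at |r| = 1 and the later one dropped
  sc2 <- collinearity_screen(data.frame(a, a2 = a, b))
  expect_identical(sc2$retained, c("a", "b"))
  expect_equal(abs(sc2$dropped$r), 1, tolerance = 1e-12)
  # worked 3-predictor set with genuine correlation structure
  d <- rnorm(n, sd = 0.8) + 0.5 * a
  X <- data.frame(a, b, d)
  sc3 <- collinearity_screen(X, threshold_r = 0.95)
  expect_equal(unname(sc3$vif), unname(vif_oracle(X)), tolerance = 1e-10)
})

test_that("Gamma GLZ fit agrees with stats::glm and a direct MLE oracle", {
  set.seed(55)
  n <- 120
  x1 <- rnorm(n); x2 <- runif(n)
  mu <- exp(1 + 0.5 * x1 - 0.8 * x2)
  y <- rgamma(n, shape = 5, rate = 5 / mu)
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  mine <- fit_gamma_glz(y, X)
  ref <- glm(y ~ x1 + x2, family = Gamma(link = "log"))
  expect_equal(unname(mine$coefficients), unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(mine$aic, AIC(ref), tolerance = 1e-8)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(mine$se),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-6)
  expect_equal(mine$df, attr(logLik(ref), "df"))
  # deviance equals an independent direct minimisation of the Gamma deviance
  devfun <- function(beta) {
    m <- exp(drop(X %*% beta))
    2 * sum(-log(y / m) + (y - m) / m)
  }
  o <- suppressWarnings(optim(c(log(mean(y)), 0, 0), devfun, method = "BFGS",
                              control = list(reltol = 1e-14, maxit = 500)))
  expect_equal(mine$deviance, o$value, tolerance = 1e-6)
  # intercept-only closed form on a constant response (perfect fit: glm.fit
  # warns about its degenerate likelihood, which is expected here)
  cst <- suppressWarnings(
    fit_gamma_glz(rep(3.7, 10), matrix(1, 10, 1,
                                       dimnames = list(NULL, "(Intercept)"))))
  expect_equal(unname(cst$coefficients[1]), log(3.7), tolerance = 1e-9)
  expect_error(fit_gamma_glz(c(-1, 2, 3), matrix(1, 3, 1)), "positive")
})

test_that("Gamma GLZ recovers known coefficients within 2 SE", {
  set.seed(57)
  n <- 800
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  beta <- c(2, 0.6, -1.0)
  mu <- exp(beta[1] + beta[2] * x1 + beta[3] * x2)
  y <- rgamma(n, shape = 6, rate = 6 / mu)
  f <- fit_gamma_glz(y, cbind("(Intercept)" = 1, x1 = x1, x2 = x2))
  for (j in 1:3) {
    expect_lt(abs(f$coefficients[j] - beta[j]), 2 * f$se[j])
  }
})

test_that("candidate enumeration is complete, unique and marginal", {
  free <- c("lake", "species", "temp", "light", "pressure", "wind",
            "biomass", "nee")
  cand <- enumerate_candidates(free)
  expect_length(cand, 2304L)                    # 2^8 * 3 * 3
  keys <- vapply(cand, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  expect_identical(anyDuplicated(keys), 0L)
  # quadratic never appears without its linear parent
  bad <- vapply(cand, function(s) {
    ("date2" %in% s && !"date1" %in% s) ||
      ("time2" %in% s && !"time1" %in% s)
  }, logical(1))
  expect_false(any(bad))
  # single free term, no polynomial groups: null and full model only
  expect_length(enumerate_candidates("x", poly = list()), 2L)
})

test_that("Akaike weights normalise and rank by AIC", {
  expect_equal(akaike_weights(rep(10, 4)), rep(0.25, 4))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  set.seed(59)
  a <- runif(30, 100, 140)
  w <- akaike_weights(a)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_identical(which.max(w), which.min(a))
  expect_error(akaike_weights(c(1, NA)), "non-finite")
})

test_that("model averaging follows the hand-computed formulas", {
  f1 <- list(coefficients = c("(Intercept)" = 1, a = 2),
             se = c("(Intercept)" = 0.1, a = 0.2))
  f2 <- list(coefficients = c("(Intercept)" = 0.5),
             se = c("(Intercept)" = 0.05))
  w <- c(0.6, 0.4)
  tab <- model_average(list(f1, f2), w, terms_all = c("(Intercept)", "a"))
  # intercept: in both models
  expect_equal(tab$estimate[1], 0.6 * 1 + 0.4 * 0.5, tolerance = 1e-12)
  expect_equal(tab$ri[1], 1)
  # term a: full average substitutes 0 where absent
  mae <- 0.6 * 2
  expect_equal(tab$estimate[2], mae, tolerance = 1e-12)
  expect_equal(tab$se[2],
               0.6 * sqrt(0.2^2 + (2 - mae)^2) + 0.4 * sqrt(0 + mae^2),
               tolerance = 1e-12)
  expect_equal(tab$ri[2], 0.6)
  expect_equal(tab$ci_lower[2], mae - 1.96 * tab$se[2], tolerance = 1e-12)
  # conditional averaging renormalises over the containing models
  tabc <- model_average(list(f1, f2), w, terms_all = c("(Intercept)", "a"),
                        average = "conditional")
  expect_equal(tabc$estimate[2], 2, tolerance = 1e-12)
  expect_equal(tabc$se[2], 0.2, tolerance = 1e-12)
  # single candidate: averaged estimates are its coefficients, RI = 1
  tab1 <- model_average(list(f1), 1)
  expect_equal(unname(tab1$estimate), unname(f1$coefficients))
  expect_true(all(tab1$ri == 1))
})

test_that("flux_model_average reproduces the study structure end to end", {
  study <- simulate_chamber_study(small_config(seed = 61))
  fl <- estimate_fluxes(study)
  fl <- fl[!fl$ebullition, ]
  avg <- flux_model_average(thin_by_day(fl),
                            terms = c("lake", "species", "air_temp_c",
                                      "wind"))
  # 2^4 * 3 * 3 candidates
  expect_identical(avg$n_models, 144L)
  expect_equal(sum(avg$candidates$weight), 1, tolerance = 1e-10)
  expect_true(all(avg$candidates$delta >= 0))
  expect_equal(min(avg$candidates$delta), 0)
  tab <- avg$coefficients
  expect_true(all(tab$ri >= 0 & tab$ri <= 1))
  expect_true(all(tab$ci_lower <= tab$estimate & tab$estimate <= tab$ci_upper))
  # lake and temperature dominate by construction (multiplier 3, coef > 0)
  expect_equal(tab$ri[tab$term == "lake"], 1, tolerance = 1e-6)
  expect_equal(tab$ri[tab$term == "air_temp_c"], 1, tolerance = 1e-6)
  expect_lt(tab$estimate[tab$term == "lake"], 0)      # Erssjon vs Foljesjon
  expect_gt(tab$estimate[tab$term == "air_temp_c"], 0)
  # predictions on the training data use the averaged coefficients
  eta <- predict(avg, thin_by_day(fl), type = "link")
  expect_equal(exp(eta), predict(avg, thin_by_day(fl)), tolerance = 1e-12)
  expect_equal(length(eta), avg$n)
})

test_that("autocorrelation check finds AR structure and not white noise", {
  set.seed(63)
  wn <- replicate(200, autocorrelation_check(rnorm(24))$order)
  ar1 <- replicate(200, {
    autocorrelation_check(as.numeric(arima.sim(list(ar = 0.8), 24)))$order
  })
  # AIC order selection overfits white noise at a known rate; order 0 is
  # still the clear modal choice, and genuine AR(1) is nearly always found
  expect_gt(mean(wn == 0), 0.6)
  expect_gt(mean(wn == 0), mean(wn == 1))
  expect_gte(mean(ar1 >= 1), 0.9)
  deg <- autocorrelation_check(rep(2, 12))
  expect_identical(deg$order, 0L)
  expect_true(deg$degenerate)
  expect_error(autocorrelation_check(1:4), "at least 6")
})
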