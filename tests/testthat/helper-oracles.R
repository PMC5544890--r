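# Independent oracles used to cross-check the implementation.
# These deliberately use different code paths (normal equations, aov
# decompositions, per-predictor regressions, direct likelihood search)
# than the package internals.

# OLS via the normal equations, times in days
ols_oracle <- function(times_s, ppm) {
  x <- times_s / 86400
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% ppm)
  fitted <- X %*% beta
  ss_res <- sum((ppm - fitted)^2)
  ss_tot <- sum((ppm - mean(ppm))^2)
  list(intercept = beta[1], slope = beta[2],
       r2 = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

# two-way ANOVA mean squares via aov(); matrix oriented as the package
# expects (rows = series, cols = classes); targets are the classes
icc_oracle <- function(mat) {
  R <- t(mat)
  n <- nrow(R); k <- ncol(R)
  d <- data.frame(y = as.vector(R),
                  target = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  list(single = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
       average = (msr - mse) / (msr + (msc - mse) / n))
}

# VIF by regressing each predictor on the others
vif_oracle <- function(X) {
  X <- as.data.frame(X)
  sapply(names(X), function(v) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(names(X), v), v),
                            data = X))$r.squared
    1 / (1 - r2)
  })
}

# moles of air in the chamber from first principles, then flux by hand
flux_oracle <- function(slope_ppm_d, p_atm, t_k, volume_l, area_m2) {
  moles <- p_atm * volume_l / (0.082056 * t_k)
  slope_ppm_d * 1e-6 * moles / area_m2 * 1000
}

# minimal study configuration used where full size is not needed
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             dates = as.Date(c("2014-06-09", "2014-07-20", "2014-08-29",
                               "2014-10-12")),
             seasonal_temp_c = c(15, 18, 14, 7),
             hourly_occasions = c(1L, 0L),
             drop_series = 0L,
             ...)
}
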