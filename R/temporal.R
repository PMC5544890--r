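#' Assign clock times to diel time classes
#'
#' Partitions the 24-h day into `n_classes` equal half-open bins
#' (`[0, 24/n)`, `[24/n, 48/n)`, ...) and returns the 0-based class index
#' `floor(hours / (24 / n_classes))`.  With the default 10 classes each bin
#' spans 2.4 h, so a 12-measurement (2-hourly) schedule puts 1-2 values in
#' every class and a 24-measurement (hourly) schedule 2-3.
#'
#' @param clock_hours Hours since midnight, in `[0, 24)`.
#' @param n_classes Number of classes (default 10).
#' @return Integer class indices in `0:(n_classes - 1)`.
#' @export
assign_time_class <- function(clock_hours, n_classes = 10L) {
  if (any(!is.finite(clock_hours)) || any(clock_hours < 0) ||
      any(clock_hours >= 24)) {
    stop("domain error: clock time must lie in [0, 24)", call. = FALSE)
  }
  as.integer(floor(clock_hours / (24 / n_classes)))
}

#' Per-class means of one daily series
#'
#' @param clock_hours,values Paired measurement times and fluxes for one
#'   24-h series.
#' @param n_classes Number of diel classes.
#' @return Numeric vector of length `n_classes` (class 0 first); classes
#'   with no measurement are `NA`.
#' @export
class_means <- function(clock_hours, values, n_classes = 10L) {
  if (length(clock_hours) == 0) {
    stop("analysis error: empty series", call. = FALSE)
  }
  cls <- assign_time_class(clock_hours, n_classes)
  out <- rep(NA_real_, n_classes)
  m <- tapply(values, factor(cls, levels = 0:(n_classes - 1)), mean)
  out[!is.na(m)] <- m[!is.na(m)]
  out
}

#' Intra-class correlation of diel profiles (two-way, absolute agreement)
#'
#' Measures whether independent daily series agree on the diel profile:
#' time classes are the targets of the two-way ANOVA decomposition and the
#' daily series are the raters.  With between-class mean square `MSR`,
#' between-series mean square `MSC`, error mean square `MSE`, `k` series and
#' `n` classes, the single-measure absolute-agreement coefficient is
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1) MSE + (k/n)(MSC - MSE)}}
#' and the average-measure variant replaces the denominator with
#' `MSR + (MSC - MSE)/n`.  If every series has the same profile and the
#' classes differ the coefficient is 1; for unrelated series it is near 0.
#' The p-value is the F test `MSR / MSE` on `(n-1)` and `(n-1)(k-1)` df.
#'
#' @param mat Complete numeric matrix, one row per daily series, one column
#'   per time class (at least 2 of each, no `NA`).
#' @param variant Which coefficient is the headline one: `"single"`
#'   (default) or `"average"`.  Both are always computed and returned.
#' @return Object of class `"icc_result"`.
#' @export
icc_agreement <- function(mat, variant = c("single", "average")) {
  variant <- match.arg(variant)
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    stop("analysis error: ICC needs a complete matrix; drop incomplete ",
         "time classes first (see diel_icc)", call. = FALSE)
  }
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("analysis error: ICC needs at least 2 series and 2 classes",
         call. = FALSE)
  }
  R <- t(mat)                  # rows: time classes (targets); cols: series
  n <- nrow(R)
  k <- ncol(R)
  g <- mean(R)
  rm <- rowMeans(R)
  cm <- colMeans(R)
  ssr <- k * sum((rm - g)^2)
  ssc <- n * sum((cm - g)^2)
  sse <- sum((R - g)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 && msc <= 0 && mse <= 0) {
    stop("analysis error: degenerate matrix (no variance anywhere); ",
         "ICC is undefined", call. = FALSE)
  }
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  f <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(
    list(coefficient = if (variant == "single") icc1 else icck,
         variant = variant, icc_single = icc1, icc_average = icck,
         n_series = k, k_classes = n,
         ms = c(between_class = msr, between_series = msc, error = mse),
         f = f, df1 = df1, df2 = df2, p_value = p),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat("Intra-class correlation of diel profiles",
      "(two-way, absolute agreement)\n")
  cat(sprintf("  %s measures: %.3f  (single %.3f, average %.3f)\n",
              x$variant, x$coefficient, x$icc_single, x$icc_average))
  cat(sprintf("  %d daily series x %d time classes; F(%d, %d) = %.2f, P = %.3g\n",
              x$n_series, x$k_classes, x$df1, x$df2, x$f, x$p_value))
  if (!is.null(attr(x, "dropped_classes")) && attr(x, "dropped_classes") > 0) {
    cat(sprintf("  (%d time classes dropped as missing in >= 1 series)\n",
                attr(x, "dropped_classes")))
  }
  invisible(x)
}

#' Diel agreement across the daily series of a flux table
#'
#' Bins each daily series (lake x species x date) of a [estimate_fluxes()]
#' table into diel time classes, averages within class, drops any class
#' missing in at least one series (with a warning giving the count), and
#' computes the agreement ICC ([icc_agreement()]).  Ebullition-flagged rows
#' are excluded first.
#'
#' @param fluxes A flux table with `lake`, `species`, `date`, `clock_hours`
#'   and the flux column.
#' @param n_classes Number of diel classes (default 10).
#' @param variant Headline ICC variant, `"single"` or `"average"`.
#' @param flux_col Name of the flux column.
#' @return An `"icc_result"`, with attribute `dropped_classes`.
#' @export
diel_icc <- function(fluxes, n_classes = 10L,
                     variant = c("single", "average"),
                     flux_col = "ch4_flux_mmol_m2_d") {
  variant <- match.arg(variant)
  if ("ebullition" %in% names(fluxes)) {
    fluxes <- fluxes[!fluxes$ebullition, ]
  }
  key <- paste(fluxes$lake, fluxes$species, fluxes$date, sep = " | ")
  series <- split(fluxes, key)
  mat <- t(vapply(series,
                  function(s) class_means(s$clock_hours, s[[flux_col]],
                                          n_classes),
                  numeric(n_classes)))
  complete <- colSums(is.na(mat)) == 0
  dropped <- sum(!complete)
  if (dropped > 0) {
    warning("dropping ", dropped, " time class(es) missing in at least one ",
            "series", call. = FALSE)
  }
  res <- icc_agreement(mat[, complete, drop = FALSE], variant = variant)
  attr(res, "dropped_classes") <- dropped
  res
}

#' Mean and 95% confidence interval of one day's fluxes
#'
#' The diel mean with a t-based 95% CI (`mean +- t[0.975, n-1] * SE`); the
#' t quantile, not 1.96, because daily series hold only 7-24 values.  The CI
#' is undefined (`NA`) for a single value.
#'
#' @param values Flux values of one daily series (ebullition-excluded).
#' @return List `mean`, `n`, `ci_half_width`.
#' @export
daily_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) return(list(mean = NA_real_, n = 0L, ci_half_width = NA_real_))
  m <- mean(values)
  ci <- if (n >= 2) {
    stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  } else {
    NA_real_
  }
  list(mean = m, n = n, ci_half_width = ci)
}

#' Daily (24-h) summaries of a flux table
#'
#' One row per lake x species x date: diel mean flux with its 95% CI
#' ([daily_summary()]), plus daily means of any driver columns present
#' (air temperature, wind, light, NEE) for use in [daily_regressions()].
#' Ebullition-flagged rows are excluded.
#'
#' @inheritParams diel_icc
#' @param drivers Driver columns to average per day, if present.
#' @return Data frame of daily summaries.
#' @export
daily_summaries <- function(fluxes, flux_col = "ch4_flux_mmol_m2_d",
                            drivers = c("air_temp_c", "wind", "light",
                                        "co2_flux_mmol_m2_d")) {
  if ("ebullition" %in% names(fluxes)) {
    fluxes <- fluxes[!fluxes$ebullition, ]
  }
  drivers <- intersect(drivers, names(fluxes))
  key <- unique(fluxes[c("lake", "species", "date")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    s <- fluxes[fluxes$lake == key$lake[i] &
                  fluxes$species == key$species[i] &
                  fluxes$date == key$date[i], ]
    ds <- daily_summary(s[[flux_col]])
    out <- data.frame(lake = key$lake[i], species = key$species[i],
                      date = key$date[i], mean_flux = ds$mean, n = ds$n,
                      ci95_half_width = ds$ci_half_width)
    for (d in drivers) out[[paste0("mean_", d)]] <- mean(s[[d]], na.rm = TRUE)
    out
  })
  out <- do.call(rbind, rows)
  out[order(out$lake, out$species, out$date), , drop = FALSE]
}

#' Ordinary least-squares regression of daily means
#'
#' Simple linear regression of daily mean flux on a daily mean driver, with
#' the two-sided p-value of the slope and the adjusted R2.  Slopes with
#' `P < 0.05` are conventionally read as significant.
#'
#' @param x Daily driver means (n >= 3, non-constant).
#' @param y Daily flux means.
#' @return List with `slope`, `intercept`, `p_value`, `adj_r_squared`, `n`.
#' @export
fit_daily_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop("analysis error: regression needs at least 3 daily means",
         call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("analysis error: zero variance in the driver", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = unname(s$coefficients[2, 4]),
       adj_r_squared = s$adj.r.squared,
       n = length(x))
}

#' Regress daily mean flux on each daily mean driver
#'
#' @param daily Output of [daily_summaries()].
#' @param response Daily flux column.
#' @param drivers Daily driver columns to regress on (those present).
#' @return Data frame: one row per driver with slope, intercept, p-value,
#'   adjusted R2 and n.
#' @export
daily_regressions <- function(daily, response = "mean_flux",
                              drivers = c("mean_air_temp_c", "mean_wind",
                                          "mean_light",
                                          "mean_co2_flux_mmol_m2_d")) {
  drivers <- intersect(drivers, names(daily))
  rows <- lapply(drivers, function(d) {
    r <- fit_daily_regression(daily[[d]], daily[[response]])
    data.frame(driver = d, slope = r$slope, intercept = r$intercept,
               p_value = r$p_value, adj_r_squared = r$adj_r_squared,
               n = r$n)
  })
  do.call(rbind, rows)
}
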