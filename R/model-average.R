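#' Thin a 24-measurement day to 12
#'
#' Early 24-h occasions were sampled hourly (24 enclosures) while later ones
#' were sampled every second hour (12).  To keep sampling intensity even
#' along the seasonal gradient, a day with exactly 24 measurements keeps
#' every second value (the 1st, 3rd, ... in time order); any other count is
#' returned unchanged — the rule applies only to full hourly days.
#'
#' @param x A vector, or a data frame of one day's measurements ordered by
#'   time.
#' @return The thinned object.
#' @export
thin_series <- function(x) {
  n <- NROW(x)
  if (n != 24L) return(x)
  idx <- seq(1L, 23L, by = 2L)
  if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}

#' Apply [thin_series()] within each daily series of a table
#'
#' @param df Measurement table.
#' @param by Columns identifying a daily series.
#' @param time_col Column giving within-day time order.
#' @return The table with every full 24-row series thinned to 12.
#' @export
thin_by_day <- function(df, by = c("lake", "species", "date"),
                        time_col = "clock_hours") {
  key <- interaction(df[by], drop = TRUE)
  parts <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    idx <- idx[order(df[[time_col]][idx])]
    thin_series(df[idx, , drop = FALSE])
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Standardize a predictor to mean 0, SD 0.5
#'
#' `(x - mean(x)) / (2 * sd(x))` with the sample SD (n - 1 denominator).
#' Halving the usual z-scale puts continuous coefficients on a footing
#' comparable with 0/1 binary predictors, so model-averaged estimates can
#' be compared across terms.  The centring and scaling constants are
#' attached as attributes for later prediction.
#'
#' @param x Numeric vector with non-zero variance.
#' @return Standardized vector with attributes `center` and `scale`
#'   (`scale` is `2 * sd(x)`).
#' @export
standardize_half_sd <- function(x) {
  if (any(!is.finite(x))) {
    stop("configuration error: predictor contains non-finite values",
         call. = FALSE)
  }
  s <- stats::sd(x)
  if (s == 0) {
    stop("configuration error: zero variance predictor cannot be ",
         "standardized", call. = FALSE)
  }
  out <- (x - mean(x)) / (2 * s)
  attr(out, "center") <- mean(x)
  attr(out, "scale") <- 2 * s
  out
}

#' Screen predictors for collinearity
#'
#' Two-stage screen mirroring common practice before all-subsets model
#' averaging: (1) for every pair with `|r| > threshold_r`, drop the member
#' that comes later in the `priority` order (repeatedly, strongest pair
#' first); (2) report variance-inflation factors on the retained set,
#' computed as the diagonal of the inverse correlation matrix
#' (equivalently `1 / (1 - R2_j)` from regressing each retained predictor
#' on the others), warning if any exceeds `vif_max`.
#'
#' @param predictors Numeric data frame or matrix of candidate predictors.
#' @param threshold_r Pairwise correlation threshold (default 0.7).
#' @param vif_max VIF warning level (default 3).
#' @param priority Column names in decreasing priority; defaults to input
#'   order.
#' @return List with `retained` (names), `dropped` (data frame: variable,
#'   correlated_with, r) and `vif` (named vector).
#' @export
collinearity_screen <- function(predictors, threshold_r = 0.7, vif_max = 3,
                                priority = colnames(predictors)) {
  X <- as.matrix(predictors)
  if (ncol(X) < 2) {
    stop("analysis error: need at least 2 predictors to screen",
         call. = FALSE)
  }
  vars <- colnames(X)
  dropped <- data.frame(variable = character(0),
                        correlated_with = character(0), r = numeric(0))
  repeat {
    C <- stats::cor(X[, vars, drop = FALSE])
    diag(C) <- 0
    mx <- max(abs(C))
    if (mx <= threshold_r) break
    ij <- which(abs(C) == mx, arr.ind = TRUE)[1, ]
    a <- vars[ij[1]]; b <- vars[ij[2]]
    # drop whichever ranks lower in the priority list
    loser <- if (match(a, priority) > match(b, priority)) a else b
    winner <- setdiff(c(a, b), loser)
    dropped <- rbind(dropped,
                     data.frame(variable = loser, correlated_with = winner,
                                r = C[ij[1], ij[2]]))
    vars <- setdiff(vars, loser)
    if (length(vars) < 2) break
  }
  Cr <- stats::cor(X[, vars, drop = FALSE])
  inv <- tryCatch(solve(Cr), error = function(e) {
    stop("analysis error: perfect collinearity remains among: ",
         paste(vars, collapse = ", "), call. = FALSE)
  })
  vif <- stats::setNames(diag(inv), vars)
  if (any(vif > vif_max)) {
    warning("VIF above ", vif_max, " for: ",
            paste(vars[vif > vif_max], collapse = ", "), call. = FALSE)
  }
  list(retained = vars, dropped = dropped, vif = vif)
}

# Gamma(log) family AIC as used by stats::glm: likelihood evaluated at the
# deviance-based dispersion, plus 2 for estimating the shape parameter.
gamma_family_aic <- function(y, mu, dev) {
  n <- length(y)
  disp <- dev / n
  -2 * sum(stats::dgamma(y, shape = 1 / disp, scale = mu * disp,
                         log = TRUE)) + 2
}

#' Fit one Gamma log-link candidate model
#'
#' Fits a generalized linear model with Gamma errors and log link by
#' iteratively reweighted least squares (via [stats::glm.fit()], converged
#' when the relative deviance change drops below 1e-8, at most 100
#' iterations).  The information criterion counts every regression
#' coefficient plus the Gamma shape parameter, with the likelihood
#' evaluated at the deviance-based dispersion — identical to
#' `stats::AIC()` on the corresponding `glm()` fit.  Standard errors use
#' the Pearson-dispersion covariance.
#'
#' @param y Positive response vector.
#' @param X Design matrix, first column the intercept; must be full rank.
#' @param terms Term names (default non-intercept column names).
#' @return Object of class `"gamma_glz"`: coefficients, `se`, `deviance`,
#'   `logLik`, `aic`, `aicc`, `df` (coefficients + shape),
#'   `dispersion` (Pearson), `shape` (deviance-based 1/dispersion), `n`.
#' @export
fit_gamma_glz <- function(y, X, terms = colnames(X)[-1]) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("domain error: Gamma response must be positive", call. = FALSE)
  }
  X <- as.matrix(X)
  fit <- stats::glm.fit(X, y, family = stats::Gamma(link = "log"),
                        control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    stop("analysis error: IRLS did not converge in 100 iterations",
         call. = FALSE)
  }
  rank <- fit$rank
  if (rank < ncol(X)) {
    stop("analysis error: design matrix not full rank (",
         paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "),
         " aliased)", call. = FALSE)
  }
  n <- length(y)
  mu <- fit$fitted.values
  dev <- fit$deviance
  # a (near-)perfect fit has a degenerate likelihood; report -Inf AIC
  fam_aic <- if (dev <= sqrt(.Machine$double.eps)) -Inf else {
    gamma_family_aic(y, mu, dev)
  }
  aic <- fam_aic + 2 * rank
  p <- rank + 1                       # coefficients + shape
  aicc <- aic + 2 * p * (p + 1) / (n - p - 1)
  phi <- sum((y - mu)^2 / mu^2) / (n - rank)
  Rm <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
  Rm[lower.tri(Rm)] <- 0
  cov_unscaled <- chol2inv(Rm)
  piv <- fit$qr$pivot[seq_len(rank)]
  se <- numeric(ncol(X))
  se[piv] <- sqrt(diag(cov_unscaled) * phi)
  names(se) <- colnames(X)
  structure(
    list(coefficients = fit$coefficients, se = se, terms = terms,
         deviance = dev, logLik = (2 - fam_aic) / 2, aic = aic, aicc = aicc,
         df = p, dispersion = phi, shape = n / dev, n = n,
         fitted = mu),
    class = "gamma_glz"
  )
}

#' Enumerate all candidate term sets nested in the full model
#'
#' Every subset of the free terms is crossed with, for each polynomial
#' group (date, time of day), the three marginality-respecting options:
#' absent, linear only, or linear plus quadratic.  The intercept is always
#' included and is not listed.  For 8 free terms and both polynomial groups
#' this gives `2^8 * 3 * 3 = 2304` candidates.
#'
#' @param free_terms Character vector of freely switchable terms.
#' @param poly Named list of polynomial groups, each a character vector
#'   `c(linear, quadratic)`; the quadratic never appears without its linear
#'   parent.
#' @return List of character vectors (term sets), in a deterministic order.
#' @export
enumerate_candidates <- function(free_terms,
                                 poly = list(date = c("date1", "date2"),
                                             time = c("time1", "time2"))) {
  nf <- length(free_terms)
  subsets <- lapply(0:(2^nf - 1), function(m) {
    free_terms[bitwAnd(m, bitwShiftL(1L, seq_len(nf) - 1L)) > 0L]
  })
  opts <- lapply(poly, function(p) {
    list(character(0), p[1], p[1:2])
  })
  out <- subsets
  for (o in opts) {
    out <- unlist(lapply(out, function(s) {
      lapply(o, function(extra) c(s, extra))
    }), recursive = FALSE)
  }
  out
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`: the relative support for each candidate.
#'
#' @param aic Vector of finite information-criterion values.
#' @return Weights summing to 1; the minimum-AIC model has the largest.
#' @export
akaike_weights <- function(aic) {
  if (any(!is.finite(aic))) {
    stop("analysis error: non-finite AIC values", call. = FALSE)
  }
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Model-averaged coefficients over a candidate set
#'
#' Combines the candidate fits with their Akaike weights.  Under the
#' default full (zero-substitution) averaging a term absent from a model
#' contributes a coefficient of 0, shrinking weakly supported terms toward
#' zero; conditional averaging renormalises over only the models containing
#' the term.  The unconditional standard error follows the
#' weighted-variance-plus-between-model-spread formula
#' `SE_j = sum_i w_i * sqrt(se_ij^2 + (b_ij - MAE_j)^2)`; `z = |MAE|/SE`;
#' the 95% CI is `MAE +- 1.96 SE`; the relative importance of a term is the
#' summed weight of the models containing it.
#'
#' @param fits List of [fit_gamma_glz()] results (or any objects with named
#'   `coefficients` and `se`).
#' @param weights Akaike weights, same length.
#' @param terms_all Term order for the output (default: union in first-seen
#'   order).
#' @param average `"full"` (default) or `"conditional"`.
#' @return Data frame: `term`, `estimate` (MAE), `se`, `z`, `ci_lower`,
#'   `ci_upper`, `ri`.
#' @export
model_average <- function(fits, weights, terms_all = NULL,
                          average = c("full", "conditional")) {
  average <- match.arg(average)
  if (length(fits) == 0) {
    stop("analysis error: no candidate fits to average", call. = FALSE)
  }
  if (length(weights) != length(fits)) {
    stop("analysis error: one weight per candidate required", call. = FALSE)
  }
  if (is.null(terms_all)) {
    terms_all <- unique(unlist(lapply(fits, function(f) {
      names(f$coefficients)
    })))
  }
  m <- length(fits)
  p <- length(terms_all)
  B <- matrix(0, m, p, dimnames = list(NULL, terms_all))
  S <- matrix(0, m, p, dimnames = list(NULL, terms_all))
  Inc <- matrix(FALSE, m, p, dimnames = list(NULL, terms_all))
  for (i in seq_len(m)) {
    cf <- fits[[i]]$coefficients
    B[i, names(cf)] <- cf
    S[i, names(cf)] <- fits[[i]]$se[names(cf)]
    Inc[i, names(cf)] <- TRUE
  }
  ri <- colSums(weights * Inc)
  est <- se <- numeric(p)
  for (j in seq_len(p)) {
    if (average == "full") {
      w <- weights
      b <- B[, j]; s <- S[, j]
    } else {
      idx <- Inc[, j]
      if (!any(idx)) { est[j] <- NA; se[j] <- NA; next }
      w <- weights[idx] / sum(weights[idx])
      b <- B[idx, j]; s <- S[idx, j]
    }
    est[j] <- sum(w * b)
    se[j] <- sum(w * sqrt(s^2 + (b - est[j])^2))
  }
  data.frame(term = terms_all, estimate = est, se = se,
             z = ifelse(se > 0, abs(est) / se, NA_real_),
             ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
             ri = ri)
}

#' All-subsets Gamma GLZ model averaging of chamber fluxes
#'
#' The central fitting function: models every (ebullition-free, thinned)
#' flux measurement with a Gamma log-link generalized linear model,
#' enumerates all candidate models nested in the full model
#' ([enumerate_candidates()]), ranks them by AIC, and reports Akaike-weight
#' model-averaged coefficients with unconditional SEs, 95% CIs and relative
#' importance ([model_average()]).  Continuous predictors are standardized
#' to mean 0, SD 0.5 ([standardize_half_sd()]) so their coefficients are
#' comparable with the 0/1 lake and species indicators; date (day of study)
#' and time of day enter with marginality-respecting quadratics built after
#' standardization.
#'
#' @param data Data frame of flux measurements (one row per enclosure).
#' @param response Positive flux column to model.
#' @param terms Free model terms: names of columns.  Binary columns are
#'   encoded 0/1 against `reference`; all other terms are standardized.
#' @param binary Which terms are categorical two-level factors.
#' @param reference Named character vector of reference levels for the
#'   binary terms (the indicator is 1 for the non-reference level).
#' @param date_col,time_col Columns providing the date and clock time for
#'   the polynomial seasonal/diel terms; `NULL` omits that group.
#' @param average Averaging variant, `"full"` (default) or
#'   `"conditional"`.
#' @param ic `"AIC"` (default) or `"AICc"`.
#' @return Object of class `"flux_avg"`; see [print.flux_avg()],
#'   [summary.flux_avg()], [coef.flux_avg()], [predict.flux_avg()].
#' @export
flux_model_average <- function(data, response = "ch4_flux_mmol_m2_d",
                               terms = c("lake", "species", "air_temp_c",
                                         "light", "pressure_atm", "wind",
                                         "biomass_gdw_m2",
                                         "co2_flux_mmol_m2_d"),
                               binary = c("lake", "species"),
                               reference = c(lake = "Foljesjon",
                                             species = "C. rostrata"),
                               date_col = "date", time_col = "clock_hours",
                               average = c("full", "conditional"),
                               ic = c("AIC", "AICc")) {
  average <- match.arg(average)
  ic <- match.arg(ic)
  miss <- setdiff(c(response, terms), names(data))
  if (length(miss)) {
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("domain error: response must be positive for the Gamma model",
         call. = FALSE)
  }
  n <- nrow(data)
  std <- list()
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (tm in terms) {
    v <- data[[tm]]
    if (tm %in% binary) {
      ref <- reference[[tm]]
      lev <- unique(as.character(v))
      if (!ref %in% lev) {
        stop("configuration error: reference level '", ref,
             "' not found in '", tm, "'", call. = FALSE)
      }
      if (length(lev) != 2) {
        stop("configuration error: binary term '", tm, "' has ",
             length(lev), " levels", call. = FALSE)
      }
      col <- as.numeric(as.character(v) != ref)
      attr(col, "level") <- setdiff(lev, ref)
    } else {
      col <- standardize_half_sd(as.numeric(v))
      std[[tm]] <- list(center = attr(col, "center"),
                        scale = attr(col, "scale"))
    }
    X <- cbind(X, stats::setNames(data.frame(as.numeric(col)), tm))
    X <- as.matrix(X)
  }
  poly <- list()
  if (!is.null(date_col)) {
    d1 <- standardize_half_sd(as.numeric(data[[date_col]]))
    std[["date1"]] <- list(center = attr(d1, "center"),
                           scale = attr(d1, "scale"))
    X <- cbind(X, date1 = as.numeric(d1), date2 = as.numeric(d1)^2)
    poly$date <- c("date1", "date2")
  }
  if (!is.null(time_col)) {
    t1 <- standardize_half_sd(as.numeric(data[[time_col]]))
    std[["time1"]] <- list(center = attr(t1, "center"),
                           scale = attr(t1, "scale"))
    X <- cbind(X, time1 = as.numeric(t1), time2 = as.numeric(t1)^2)
    poly$time <- c("time1", "time2")
  }

  candidates <- enumerate_candidates(terms, poly)
  fits <- lapply(candidates, function(tr) {
    fit_gamma_glz(y, X[, c("(Intercept)", tr), drop = FALSE], terms = tr)
  })
  aic <- vapply(fits, function(f) if (ic == "AICc") f$aicc else f$aic,
                numeric(1))
  w <- akaike_weights(aic)
  tab <- model_average(fits, w, terms_all = colnames(X), average = average)
  cand_df <- data.frame(
    model = vapply(candidates, function(tr) {
      if (length(tr)) paste(tr, collapse = "+") else "(intercept only)"
    }, character(1)),
    df = vapply(fits, function(f) f$df, numeric(1)),
    aic = aic, delta = aic - min(aic), weight = w)
  structure(
    list(coefficients = tab, candidates = cand_df,
         best = fits[[which.min(aic)]],
         full = fits[[length(fits)]],
         n = n, n_models = length(fits), response = response,
         terms = terms, binary = binary, reference = reference,
         average = average, ic = ic, standardization = std,
         date_col = date_col, time_col = time_col,
         design = colnames(X)),
    class = "flux_avg"
  )
}

#' @export
print.flux_avg <- function(x, digits = 3, ...) {
  cat("Gamma GLZ (log link) all-subsets", x$ic, "model averaging —",
      x$average, "average\n")
  cat(sprintf("  %d observations, %d candidate models\n", x$n, x$n_models))
  tab <- x$coefficients
  out <- data.frame(MAE = round(tab$estimate, digits),
                    SE = round(tab$se, digits),
                    z = round(tab$z, digits),
                    CI_lower = round(tab$ci_lower, digits),
                    CI_upper = round(tab$ci_upper, digits),
                    RI = round(tab$ri, 2),
                    row.names = tab$term)
  print(out)
  if (length(x$reference)) {
    cat("  binary terms are 1 for the non-reference level; reference:",
        paste(names(x$reference), "=", x$reference, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
#' @rdname print.flux_avg
#' @param object,x A `"flux_avg"`.
#' @param n_top Number of top-ranked candidate models to show.
#' @param digits,... Formatting.
summary.flux_avg <- function(object, n_top = 5, ...) {
  ord <- order(object$candidates$aic)
  structure(list(avg = object,
                 top = object$candidates[ord[seq_len(min(n_top,
                                                         nrow(object$candidates)))], ]),
            class = "summary.flux_avg")
}

#' @export
print.summary.flux_avg <- function(x, ...) {
  print(x$avg)
  cat("\nTop candidate models by", x$avg$ic, "\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.flux_avg <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Predict from a model-averaged Gamma GLZ
#'
#' Applies the stored standardization to `newdata`, builds the design row
#' by row (including the quadratic date/time columns) and returns the
#' model-averaged linear predictor or its exponential (the flux scale).
#'
#' @param object A `"flux_avg"`.
#' @param newdata Data frame with the original predictor columns.
#' @param type `"response"` (flux scale, default) or `"link"`.
#' @param ... Unused.
#' @export
predict.flux_avg <- function(object, newdata,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  n <- nrow(newdata)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (tm in object$terms) {
    v <- newdata[[tm]]
    if (tm %in% object$binary) {
      col <- as.numeric(as.character(v) != object$reference[[tm]])
    } else {
      st <- object$standardization[[tm]]
      col <- (as.numeric(v) - st$center) / st$scale
    }
    X <- cbind(X, stats::setNames(data.frame(col), tm))
    X <- as.matrix(X)
  }
  if ("date1" %in% object$design) {
    st <- object$standardization[["date1"]]
    d1 <- (as.numeric(newdata[[object$date_col]]) - st$center) / st$scale
    X <- cbind(X, date1 = d1, date2 = d1^2)
  }
  if ("time1" %in% object$design) {
    st <- object$standardization[["time1"]]
    t1 <- (as.numeric(newdata[[object$time_col]]) - st$center) / st$scale
    X <- cbind(X, time1 = t1, time2 = t1^2)
  }
  beta <- coef(object)[colnames(X)]
  eta <- drop(X %*% beta)
  if (type == "response") exp(eta) else eta
}

#' Check a day's flux sequence for autocorrelation
#'
#' Fits autoregressive models by Yule-Walker with AIC order selection over
#' orders `0..min(5, n - 2)` (the standard `stats::ar()` machinery) and
#' reports the selected order and first-lag coefficient.  Informational
#' only: no correction is applied downstream — thinning hourly days to 12
#' measurements already removes most serial dependence.
#'
#' @param x One day's flux values in time order (n >= 6).
#' @param order_max Maximum order (default `min(5, n - 2)`).
#' @return List `order`, `phi1`, `degenerate`.
#' @export
autocorrelation_check <- function(x, order_max = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 6) {
    stop("analysis error: need at least 6 points", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    return(list(order = 0L, phi1 = NA_real_, degenerate = TRUE))
  }
  if (is.null(order_max)) order_max <- min(5L, n - 2L)
  a <- stats::ar(x, aic = TRUE, order.max = order_max,
                 method = "yule-walker")
  list(order = a$order,
       phi1 = if (a$order >= 1) a$ar[1] else NA_real_,
       degenerate = FALSE)
}
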