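#' Least-squares slope of concentration against time
#'
#' Fits the ordinary least-squares line of concentration (ppm) on time for
#' one regression window.  Times are converted from seconds to days so the
#' slope is expressed in ppm per day, the unit required by the ideal-gas
#' flux conversion in [compute_flux()].  The fit quality `r2` is the squared
#' Pearson correlation of concentration with time; a window with zero
#' concentration variance is reported with `r2 = 0` (so a flat window can
#' never win best-window selection) and, by the same least-squares formula,
#' slope 0.
#'
#' @param times_s Sample times, seconds since enclosure start; strictly
#'   increasing, at least 3 values.
#' @param ppm Concentrations (ppm), same length as `times_s`.
#' @return An object of class `"window_fit"`: list with `start_s` (first
#'   sample time; overwritten with the nominal window start by
#'   [enumerate_windows()]), `slope_ppm_d`, `intercept_ppm` (value at t = 0),
#'   `r2` and `n`.
#' @export
fit_window_slope <- function(times_s, ppm) {
  n <- length(times_s)
  if (n < 3L) {
    stop("analysis error: window needs at least 3 samples, got ", n,
         call. = FALSE)
  }
  if (length(ppm) != n) {
    stop("analysis error: times and concentrations differ in length",
         call. = FALSE)
  }
  t_d <- times_s / 86400
  tc <- t_d - mean(t_d)
  sxx <- sum(tc^2)
  if (sxx == 0) {
    stop("analysis error: zero time variance in window", call. = FALSE)
  }
  pc <- ppm - mean(ppm)
  sxy <- sum(tc * pc)
  syy <- sum(pc^2)
  slope <- sxy / sxx
  structure(
    list(start_s = times_s[1L],
         slope_ppm_d = slope,
         intercept_ppm = mean(ppm) - slope * mean(t_d),
         r2 = if (syy == 0) 0 else (sxy * sxy) / (sxx * syy),
         n = n),
    class = "window_fit"
  )
}

#' Enumerate all admissible regression windows of an enclosure
#'
#' Slides a window of `spec$window_s` seconds from the end of the discard
#' period to the end of the enclosure in steps of `spec$offset_s`, fitting
#' each window with [fit_window_slope()].  Window membership uses the closed
#' interval `[start, start + window_s]` on sample times.  With the default
#' protocol (300 s enclosure, 60 s discard, 120 s windows offset by 20 s)
#' this yields seven windows.
#'
#' @param times_s,ppm The enclosure's concentration log (seconds, ppm).
#' @param spec A [chamber_spec()].
#' @param id Optional enclosure identifier used in error messages.
#' @return List of `"window_fit"` objects ordered by window start.
#' @export
enumerate_windows <- function(times_s, ppm, spec = chamber_spec(), id = NULL) {
  stopifnot(inherits(spec, "chamber_spec"))
  lab <- if (is.null(id)) "series" else paste0("enclosure '", id, "'")
  if (length(times_s) == 0 ||
      max(times_s) < spec$discard_s + spec$window_s) {
    stop("analysis error: ", lab, " too short: spans less than ",
         spec$discard_s + spec$window_s, " s", call. = FALSE)
  }
  starts <- window_starts(spec)
  fits <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    keep <- times_s >= starts[i] & times_s <= starts[i] + spec$window_s
    if (sum(keep) < 3L) {
      stop("analysis error: ", lab, ": window starting at ", starts[i],
           " s holds fewer than 3 samples", call. = FALSE)
    }
    f <- fit_window_slope(times_s[keep], ppm[keep])
    f$start_s <- starts[i]
    fits[[i]] <- f
  }
  fits
}

#' Select the best-fitting window
#'
#' Returns the window fit with the highest r2.  Ties are broken in favour
#' of the earliest window start (deterministic, and prefers data closest to
#' enclosure closure).
#'
#' @param fits Non-empty list of `"window_fit"` objects ordered by start.
#' @return The chosen `"window_fit"`.
#' @export
select_best_window <- function(fits) {
  if (length(fits) == 0) {
    stop("analysis error: no window fits to select from", call. = FALSE)
  }
  r2 <- vapply(fits, function(f) f$r2, numeric(1))
  fits[[which.max(r2)]]  # which.max returns the first maximum: earliest start
}
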