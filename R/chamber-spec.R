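#' Chamber geometry and enclosure protocol
#'
#' Describes the static (closed) chamber and the windowing protocol used to
#' turn its concentration log into a flux: physical volume and base area,
#' analyser sampling cadence, enclosure length, the initial mixing period
#' that is discarded, and the length/offset of the regression windows.
#'
#' Defaults follow a 197.4 L chamber with a 0.1849 m2 footprint, sampled
#' every 20 s for 5 min, with the first minute discarded and 2-min windows
#' offset by 20 s — which yields seven candidate windows per enclosure
#' (see [n_windows()]).
#'
#' @param volume_l Chamber volume (litres).
#' @param area_m2 Chamber base area (m2).
#' @param interval_s Analyser sampling interval (seconds).
#' @param duration_s Enclosure duration (seconds).
#' @param discard_s Initial period discarded before fitting (seconds);
#'   gas in the tubing and analyser cell needs time to reflect chamber air.
#' @param window_s Regression window length (seconds).
#' @param offset_s Offset between successive window starts (seconds);
#'   must divide `duration_s - discard_s - window_s`.
#'
#' @return An object of class `"chamber_spec"`.
#' @examples
#' spec <- chamber_spec()
#' n_windows(spec)   # 7
#' @export
chamber_spec <- function(volume_l = 197.4, area_m2 = 0.1849,
                         interval_s = 20, duration_s = 300,
                         discard_s = 60, window_s = 120, offset_s = 20) {
  chk <- function(x, nm, allow_zero = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (if (allow_zero) x < 0 else x <= 0)) {
      stop("configuration error: '", nm, "' must be a ",
           if (allow_zero) "non-negative" else "positive", " number",
           call. = FALSE)
    }
    as.numeric(x)
  }
  volume_l   <- chk(volume_l, "volume_l")
  area_m2    <- chk(area_m2, "area_m2")
  interval_s <- chk(interval_s, "interval_s")
  duration_s <- chk(duration_s, "duration_s")
  discard_s  <- chk(discard_s, "discard_s", allow_zero = TRUE)
  window_s   <- chk(window_s, "window_s")
  offset_s   <- chk(offset_s, "offset_s")
  if (discard_s + window_s > duration_s) {
    stop("configuration error: discard_s + window_s must not exceed duration_s",
         call. = FALSE)
  }
  span <- duration_s - discard_s - window_s
  if (span %% offset_s != 0) {
    stop("configuration error: offset_s must divide ",
         "duration_s - discard_s - window_s", call. = FALSE)
  }
  structure(
    list(volume_l = volume_l, area_m2 = area_m2, interval_s = interval_s,
         duration_s = duration_s, discard_s = discard_s, window_s = window_s,
         offset_s = offset_s),
    class = "chamber_spec"
  )
}

#' Number and start times of admissible regression windows
#'
#' @param spec A [chamber_spec()].
#' @return `n_windows()` the window count; `window_starts()` the vector of
#'   nominal window start times (seconds since enclosure start).
#' @export
n_windows <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  as.integer((spec$duration_s - spec$discard_s - spec$window_s) /
               spec$offset_s + 1)
}

#' @rdname n_windows
#' @export
window_starts <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  seq(spec$discard_s, spec$duration_s - spec$window_s, by = spec$offset_s)
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat("Static chamber protocol\n")
  cat(sprintf("  volume %.1f L, base area %.4f m2\n", x$volume_l, x$area_m2))
  cat(sprintf("  %g s enclosure, sampled every %g s; first %g s discarded\n",
              x$duration_s, x$interval_s, x$discard_s))
  cat(sprintf("  %g s windows offset by %g s -> %d candidate windows\n",
              x$window_s, x$offset_s, n_windows(x)))
  invisible(x)
}
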