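# Universal gas constant, L atm K-1 mol-1
R_GAS_L_ATM <- 0.082056

#' Convert a concentration slope to an areal flux
#'
#' Ideal-gas conversion of the selected regression slope (ppm per day) to a
#' methane flux in mmol m-2 d-1:
#' \deqn{F = \frac{slope}{10^6} \cdot \frac{P_{tot} V}{R T} \cdot \frac{1000}{A}}
#' i.e. the ppm/day rate times the moles of air enclosed (`P V / R T`),
#' divided by the chamber footprint, with 1000 converting mol to mmol.
#' `flux_to_slope()` is the exact inverse and is what the synthetic-data
#' generator uses to lay down concentration ramps.
#'
#' @param slope_ppm_d Regression slope, ppm per day.
#' @param pressure_atm Total air pressure (atm).
#' @param temp_k Chamber air temperature (kelvin).
#' @param spec A [chamber_spec()] supplying volume (L) and base area (m2).
#' @return Flux in mmol m-2 d-1 (signed; negative means uptake).
#' @examples
#' compute_flux(1000, 1, 293.15, chamber_spec())  # ~44.4 mmol m-2 d-1
#' @export
compute_flux <- function(slope_ppm_d, pressure_atm, temp_k,
                         spec = chamber_spec()) {
  stopifnot(inherits(spec, "chamber_spec"))
  if (!all(is.finite(slope_ppm_d))) {
    stop("domain error: slope must be finite", call. = FALSE)
  }
  if (any(!is.finite(temp_k)) || any(temp_k <= 0)) {
    stop("domain error: temperature (K) must be positive", call. = FALSE)
  }
  if (any(!is.finite(pressure_atm)) || any(pressure_atm <= 0)) {
    stop("domain error: pressure (atm) must be positive", call. = FALSE)
  }
  slope_ppm_d / 1e6 * (pressure_atm * spec$volume_l) /
    (R_GAS_L_ATM * temp_k) / spec$area_m2 * 1000
}

#' @rdname compute_flux
#' @param flux_mmol_m2_d Flux in mmol m-2 d-1.
#' @export
flux_to_slope <- function(flux_mmol_m2_d, pressure_atm, temp_k,
                          spec = chamber_spec()) {
  stopifnot(inherits(spec, "chamber_spec"))
  if (any(!is.finite(temp_k)) || any(temp_k <= 0)) {
    stop("domain error: temperature (K) must be positive", call. = FALSE)
  }
  flux_mmol_m2_d * 1e6 * (R_GAS_L_ATM * temp_k) * spec$area_m2 /
    (pressure_atm * spec$volume_l) / 1000
}

#' Convert mmol CH4 m-2 d-1 to mg CH4 m-2 h-1
#'
#' Uses the molar mass of methane, 16.04 g mol-1: `F * 16.04 / 24`.
#'
#' @param flux_mmol_m2_d Flux in mmol m-2 d-1.
#' @return Flux in mg CH4 m-2 h-1.
#' @examples
#' mmol_per_day_to_mg_per_hour(87)  # ~58
#' @export
mmol_per_day_to_mg_per_hour <- function(flux_mmol_m2_d) {
  flux_mmol_m2_d * 16.04 / 24
}

#' Normalise an areal flux by standing plant biomass
#'
#' @param flux_mmol_m2_d Flux in mmol m-2 d-1.
#' @param biomass_gdw_m2 Aboveground dry-weight biomass (g DW m-2); positive.
#' @return Flux per biomass, mmol g DW-1 d-1.
#' @export
flux_per_biomass <- function(flux_mmol_m2_d, biomass_gdw_m2) {
  if (any(!is.finite(biomass_gdw_m2)) || any(biomass_gdw_m2 <= 0)) {
    stop("domain error: biomass must be positive", call. = FALSE)
  }
  flux_mmol_m2_d / biomass_gdw_m2
}

#' Estimate aboveground dry-weight biomass in a chamber
#'
#' Two routes, matching how tall reeds and sedges are surveyed in the field.
#' For the reed species (tall, countable shoots) biomass is predicted from an
#' allometric regression of dry weight on shoot height, scaled by the shoot
#' count: `dw = count * (a + b * height)`, floored at zero.  For other
#' species (e.g. tussock sedges) the matched nearby-harvest dry weight is
#' taken directly from the record.
#'
#' @param species Species label.
#' @param shoot_count Shoots inside the chamber (reed route).
#' @param shoot_height_cm Mean shoot height, cm (reed route).
#' @param harvest_dw_gdw Dry weight (g DW m-2) of a matched harvested plot
#'   (non-reed route).
#' @param allometry Named numeric `c(a = intercept, b = slope)` of the
#'   per-shoot height-to-dry-weight regression; required for the reed route.
#' @param reed_species Label identifying the reed species.
#' @return Biomass in g DW m-2.
#' @export
estimate_biomass <- function(species, shoot_count = NULL,
                             shoot_height_cm = NULL, harvest_dw_gdw = NULL,
                             allometry = NULL,
                             reed_species = "P. australis") {
  if (identical(species, reed_species)) {
    if (is.null(allometry) || length(allometry) < 2 ||
        !all(is.finite(allometry))) {
      stop("configuration error: allometry coefficients (a, b) are required ",
           "for species '", species, "'", call. = FALSE)
    }
    if (is.null(shoot_count) || is.null(shoot_height_cm)) {
      stop("configuration error: shoot_count and shoot_height_cm are ",
           "required for species '", species, "'", call. = FALSE)
    }
    a <- unname(allometry[1]); b <- unname(allometry[2])
    return(max(0, shoot_count * (a + b * shoot_height_cm)))
  }
  if (is.null(harvest_dw_gdw) || !is.finite(harvest_dw_gdw) ||
      harvest_dw_gdw < 0) {
    stop("configuration error: harvest_dw_gdw (>= 0) is required for ",
         "species '", species, "'", call. = FALSE)
  }
  harvest_dw_gdw
}

#' Screen an enclosure for ebullition
#'
#' Bubble (ebullition) events appear as a rapid, sudden jump in CH4
#' concentration that also degrades the linearity of the whole record.  The
#' screen flags an enclosure when both hold on the retained (post-discard)
#' samples:
#' * the largest successive concentration difference exceeds `threshold_k`
#'   times the median absolute successive difference, and
#' * the least-squares fit over the whole retained record has `r2 < r2_min`.
#'
#' Both knobs are configurable; `threshold_k = Inf` disables the screen.
#' Flagged enclosures should be excluded from downstream statistics (the
#' pipeline does this).
#'
#' @param times_s,ppm The enclosure's CH4 log.
#' @param spec A [chamber_spec()] (supplies the discard period).
#' @param threshold_k Jump threshold as a multiple of the median absolute
#'   successive difference (default 10).
#' @param r2_min r2 gate on the whole retained record (default 0.9).
#' @return Logical flag.
#' @export
detect_ebullition <- function(times_s, ppm, spec = chamber_spec(),
                              threshold_k = 10, r2_min = 0.9) {
  stopifnot(inherits(spec, "chamber_spec"))
  keep <- times_s >= spec$discard_s
  tt <- times_s[keep]
  pp <- ppm[keep]
  if (length(pp) < 3L) return(FALSE)
  d <- abs(diff(pp))
  mx <- max(d)
  if (mx == 0) return(FALSE)           # flat record: nothing to flag
  med <- stats::median(d)
  ratio <- if (med > 0) mx / med else Inf
  if (!(ratio > threshold_k)) return(FALSE)
  fit_window_slope(tt, pp)$r2 < r2_min
}

#' Estimate the CH4 (and CO2) flux of one enclosure
#'
#' The per-enclosure estimator: enumerates all admissible regression windows
#' ([enumerate_windows()]), picks the one with the highest r2
#' ([select_best_window()]), converts its slope to an areal flux with the
#' ideal-gas law ([compute_flux()]), screens for ebullition
#' ([detect_ebullition()]) and, when biomass is supplied, normalises the
#' flux per g DW.  If a CO2 channel is given, its slope is fitted over the
#' same chosen window span so the paired net-ecosystem-exchange (NEE) flux
#' refers to the same period; the sign convention is positive = emission
#' into the chamber.
#'
#' @inheritParams enumerate_windows
#' @param co2_ppm Optional CO2 channel (ppm), same times.
#' @param temp_c Air temperature during the enclosure (degrees C).
#' @param pressure_atm Air pressure (atm).
#' @param biomass_gdw_m2 Optional standing biomass (g DW m-2).
#' @param ebullition_k,r2_min Detector knobs, see [detect_ebullition()].
#' @return Object of class `"chamber_flux"` with elements `ch4_flux_mmol_m2_d`,
#'   `co2_flux_mmol_m2_d`, `window` (the chosen fit), `fits`, `ebullition`,
#'   `flux_per_gdw`, `biomass_gdw_m2`, `id`.
#' @examples
#' spec <- chamber_spec()
#' t <- seq(0, 300, 20)
#' ppm <- 1.9 + flux_to_slope(10, 0.99, 288.15, spec) * t / 86400
#' chamber_flux(t, ppm, temp_c = 15, pressure_atm = 0.99, spec = spec)
#' @export
chamber_flux <- function(times_s, ch4_ppm, co2_ppm = NULL, temp_c,
                         pressure_atm, spec = chamber_spec(),
                         biomass_gdw_m2 = NA_real_, ebullition_k = 10,
                         r2_min = 0.9, id = NULL) {
  fits <- enumerate_windows(times_s, ch4_ppm, spec, id = id)
  best <- select_best_window(fits)
  temp_k <- temp_c + 273.15
  ch4_flux <- compute_flux(best$slope_ppm_d, pressure_atm, temp_k, spec)
  co2_flux <- NA_real_
  if (!is.null(co2_ppm)) {
    keep <- times_s >= best$start_s & times_s <= best$start_s + spec$window_s
    cfit <- fit_window_slope(times_s[keep], co2_ppm[keep])
    co2_flux <- compute_flux(cfit$slope_ppm_d, pressure_atm, temp_k, spec)
  }
  ebul <- detect_ebullition(times_s, ch4_ppm, spec,
                            threshold_k = ebullition_k, r2_min = r2_min)
  fpb <- if (is.finite(biomass_gdw_m2) && biomass_gdw_m2 > 0) {
    ch4_flux / biomass_gdw_m2
  } else {
    NA_real_
  }
  structure(
    list(id = id, ch4_flux_mmol_m2_d = ch4_flux,
         co2_flux_mmol_m2_d = co2_flux, window = best, fits = fits,
         ebullition = ebul, biomass_gdw_m2 = biomass_gdw_m2,
         flux_per_gdw = fpb, temp_c = temp_c, pressure_atm = pressure_atm),
    class = "chamber_flux"
  )
}

#' @export
print.chamber_flux <- function(x, ...) {
  cat("Chamber flux estimate", if (!is.null(x$id)) paste0("(", x$id, ")"), "\n")
  cat(sprintf("  CH4 flux: %.3f mmol m-2 d-1 (%.3f mg CH4 m-2 h-1)\n",
              x$ch4_flux_mmol_m2_d,
              mmol_per_day_to_mg_per_hour(x$ch4_flux_mmol_m2_d)))
  if (is.finite(x$co2_flux_mmol_m2_d)) {
    cat(sprintf("  CO2 flux (NEE): %.1f mmol m-2 d-1\n", x$co2_flux_mmol_m2_d))
  }
  cat(sprintf("  window: start %g s, slope %.1f ppm d-1, r2 %.4f (of %d)\n",
              x$window$start_s, x$window$slope_ppm_d, x$window$r2,
              length(x$fits)))
  if (is.finite(x$flux_per_gdw)) {
    cat(sprintf("  per biomass: %.4f mmol gDW-1 d-1 (%.1f g DW m-2)\n",
                x$flux_per_gdw, x$biomass_gdw_m2))
  }
  cat("  ebullition flag:", x$ebullition,
      if (x$ebullition) "(exclude from statistics)", "\n")
  invisible(x)
}

#' Estimate fluxes for every enclosure of a study
#'
#' Batch driver over a [simulate_chamber_study()] result (or any list with
#' compatible `enclosures` and `gas_log` data frames).  One output row per
#' enclosure; ebullition-flagged enclosures are kept but flagged, so no rows
#' are silently lost — downstream statistics drop them explicitly.
#'
#' @param study A `"chamber_study"` or `list(enclosures =, gas_log =)`.
#'   `enclosures` must carry `enclosure_id`, `air_temp_c`, `pressure_atm`;
#'   other columns (lake, species, date, clock_hours, biomass_gdw_m2,
#'   weather) are carried through.
#' @inheritParams chamber_flux
#' @return A data frame (class `"flux_table"`): enclosure metadata plus
#'   `ch4_flux_mmol_m2_d`, `co2_flux_mmol_m2_d`, `window_start_s`,
#'   `window_r2`, `ebullition`, `flux_per_gdw`.
#' @export
estimate_fluxes <- function(study, spec = chamber_spec(), ebullition_k = 10,
                            r2_min = 0.9) {
  enc <- study$enclosures
  logs <- study$gas_log
  if (is.null(enc) || is.null(logs)) {
    stop("format error: study must contain 'enclosures' and 'gas_log'",
         call. = FALSE)
  }
  need <- c("enclosure_id", "air_temp_c", "pressure_atm")
  miss <- setdiff(need, names(enc))
  if (length(miss)) {
    stop("format error: enclosures table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  has_co2 <- "co2_ppm" %in% names(logs)
  by_id <- split(logs, logs$enclosure_id)
  n <- nrow(enc)
  ch4 <- co2 <- ws <- r2 <- fpb <- rep(NA_real_, n)
  ebu <- rep(NA, n)
  for (i in seq_len(n)) {
    id <- enc$enclosure_id[i]
    g <- by_id[[as.character(id)]]
    if (is.null(g)) {
      stop("validation error: no gas log for enclosure '", id, "'",
           call. = FALSE)
    }
    bm <- if ("biomass_gdw_m2" %in% names(enc)) enc$biomass_gdw_m2[i] else NA
    cf <- chamber_flux(g$t_s, g$ch4_ppm,
                       co2_ppm = if (has_co2) g$co2_ppm else NULL,
                       temp_c = enc$air_temp_c[i],
                       pressure_atm = enc$pressure_atm[i], spec = spec,
                       biomass_gdw_m2 = bm, ebullition_k = ebullition_k,
                       r2_min = r2_min, id = id)
    ch4[i] <- cf$ch4_flux_mmol_m2_d
    co2[i] <- cf$co2_flux_mmol_m2_d
    ws[i] <- cf$window$start_s
    r2[i] <- cf$window$r2
    ebu[i] <- cf$ebullition
    fpb[i] <- cf$flux_per_gdw
  }
  out <- cbind(enc,
               data.frame(ch4_flux_mmol_m2_d = ch4, co2_flux_mmol_m2_d = co2,
                          window_start_s = ws, window_r2 = r2,
                          ebullition = ebu, flux_per_gdw = fpb))
  class(out) <- c("flux_table", "data.frame")
  attr(out, "spec") <- spec
  out
}
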