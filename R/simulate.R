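#' Configuration of a synthetic chamber campaign
#'
#' Describes the study design the generator emulates: two hemiboreal lakes,
#' each with one reed and one sedge site, measured over 24-h occasions from
#' June to October; the early occasions are sampled hourly (24 enclosures
#' per day), later ones every second hour (12 per day); each enclosure is a
#' 5-min chamber closure logged every 20 s.  True fluxes are log-linear in
#' air temperature with a lake multiplier (default 3x for the second lake),
#' an optional species offset (default 0: no species effect per m2), an
#' optional built-in diel modulation, and Gamma multiplicative noise.
#' Concentration logs invert the ideal-gas conversion so the injected flux
#' is exactly recoverable at zero noise.
#'
#' @param seed Integer seed; the whole study is deterministic given it.
#' @param lakes,lake_multipliers Lake labels and their positive flux
#'   multipliers (reference first).
#' @param species Two species labels (reed first).
#' @param dates Measurement occasions for the first lake (the second lake
#'   skips the first occasion and is measured one day later, mimicking an
#'   alternating field schedule).
#' @param seasonal_temp_c Seasonal mean air temperature per occasion (deg C);
#'   same length as `dates`.
#' @param lake2_skip_first Second lake starts one occasion later (so 7 + 6
#'   daily series by default).
#' @param hourly_occasions Integer pair: how many early occasions per lake
#'   are sampled hourly (24 enclosures) instead of every 2 h.
#' @param enclosures_per_day Enclosures per regular 24-h occasion; must
#'   divide 24.
#' @param chamber A [chamber_spec()].
#' @param baseline_log_flux Log flux (log mmol m-2 d-1) at 0 deg C in the
#'   reference lake.
#' @param temp_coef Per-deg-C slope on log flux.
#' @param species_offset Log-scale offset of the first species (default 0).
#' @param flux_cv Coefficient of variation of the Gamma multiplicative
#'   flux noise; 0 turns it off.
#' @param diel_flux_amplitude Relative diel modulation of the true flux
#'   (0..1), peaking mid-afternoon; default 0 (no built-in diel cycle
#'   beyond what temperature induces).
#' @param diel_temp_amplitude,temp_noise_sd Diel half-range and measurement
#'   noise of air temperature (deg C).
#' @param noise_sd_ppm,co2_noise_sd_ppm Analyser noise (ppm, per sample).
#' @param ebullition_prob Probability an enclosure receives a bubble event.
#' @param ebullition_jump_ppm Size of the injected concentration step (ppm).
#' @param ambient_ch4_ppm,ambient_co2_ppm Ambient mixing ratios at closure.
#' @param pressure_atm,pressure_sd Air pressure mean and sd (atm).
#' @param wind_meanlog,wind_sdlog Log-normal wind speed parameters (m s-1).
#' @param light_max Clear-sky midday photosynthetic photon flux
#'   (umol m-2 s-1); light is exactly zero at night.
#' @param nee_intercept,nee_light_coef,nee_sd True net-ecosystem-exchange
#'   model: `NEE = intercept + coef * light + noise` (mmol CO2 m-2 d-1,
#'   positive = emission).
#' @param max_biomass 2 x 2 matrix of peak biomass (g DW m-2), species in
#'   rows, lakes in columns.
#' @param drop_series Number of complete daily series removed at random to
#'   mimic field losses (default 1, leaving 25 complete series).
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       lakes = c("Erssjon", "Foljesjon"),
                       lake_multipliers = c(1, 3),
                       species = c("P. australis", "C. rostrata"),
                       dates = as.Date(c("2014-06-09", "2014-06-29",
                                         "2014-07-20", "2014-08-08",
                                         "2014-08-29", "2014-09-21",
                                         "2014-10-12")),
                       seasonal_temp_c = c(15, 17, 18, 16, 14, 11, 7),
                       lake2_skip_first = TRUE,
                       hourly_occasions = c(2L, 1L),
                       enclosures_per_day = 12L,
                       chamber = chamber_spec(),
                       baseline_log_flux = 0.55,
                       temp_coef = 0.075,
                       species_offset = 0,
                       flux_cv = 0.4,
                       diel_flux_amplitude = 0,
                       diel_temp_amplitude = 5,
                       temp_noise_sd = 1,
                       noise_sd_ppm = 0.02,
                       co2_noise_sd_ppm = 0.5,
                       ebullition_prob = 0.005,
                       ebullition_jump_ppm = 5,
                       ambient_ch4_ppm = 1.9,
                       ambient_co2_ppm = 410,
                       pressure_atm = 0.99,
                       pressure_sd = 0.003,
                       wind_meanlog = log(1.3),
                       wind_sdlog = 0.5,
                       light_max = 1000,
                       nee_intercept = 150,
                       nee_light_coef = -0.25,
                       nee_sd = 120,
                       max_biomass = matrix(c(25, 60, 204, 139), nrow = 2,
                                            byrow = TRUE),
                       drop_series = 1L) {
  fail <- function(field, why) {
    stop("configuration error: '", field, "' ", why, call. = FALSE)
  }
  if (length(lakes) != length(lake_multipliers)) {
    fail("lake_multipliers", "must have one multiplier per lake")
  }
  if (any(!is.finite(lake_multipliers)) || any(lake_multipliers <= 0)) {
    fail("lake_multipliers", "must be positive")
  }
  if (length(species) != 2) fail("species", "must name two species")
  if (length(seasonal_temp_c) != length(dates)) {
    fail("seasonal_temp_c", "must match 'dates' in length")
  }
  if (!is.finite(ebullition_prob) || ebullition_prob < 0 ||
      ebullition_prob > 1) {
    fail("ebullition_prob", "must lie in [0, 1]")
  }
  if (!is.finite(diel_flux_amplitude) || diel_flux_amplitude < 0 ||
      diel_flux_amplitude > 1) {
    fail("diel_flux_amplitude", "must lie in [0, 1]")
  }
  if (flux_cv < 0) fail("flux_cv", "must be non-negative")
  if (noise_sd_ppm < 0) fail("noise_sd_ppm", "must be non-negative")
  if (enclosures_per_day < 1 || 24 %% enclosures_per_day != 0) {
    fail("enclosures_per_day", "must divide 24")
  }
  if (chamber$duration_s %% chamber$interval_s != 0) {
    fail("chamber", "sampling interval must divide enclosure duration")
  }
  if (length(hourly_occasions) != length(lakes) ||
      any(hourly_occasions < 0)) {
    fail("hourly_occasions", "needs one non-negative count per lake")
  }
  if (drop_series < 0) fail("drop_series", "must be non-negative")
  dimnames(max_biomass) <- list(species, lakes)
  structure(
    list(seed = as.integer(seed), lakes = lakes,
         lake_multipliers = stats::setNames(lake_multipliers, lakes),
         species = species, dates = dates,
         seasonal_temp_c = seasonal_temp_c,
         lake2_skip_first = lake2_skip_first,
         hourly_occasions = as.integer(hourly_occasions),
         enclosures_per_day = as.integer(enclosures_per_day),
         chamber = chamber, baseline_log_flux = baseline_log_flux,
         temp_coef = temp_coef, species_offset = species_offset,
         flux_cv = flux_cv, diel_flux_amplitude = diel_flux_amplitude,
         diel_temp_amplitude = diel_temp_amplitude,
         temp_noise_sd = temp_noise_sd, noise_sd_ppm = noise_sd_ppm,
         co2_noise_sd_ppm = co2_noise_sd_ppm,
         ebullition_prob = ebullition_prob,
         ebullition_jump_ppm = ebullition_jump_ppm,
         ambient_ch4_ppm = ambient_ch4_ppm,
         ambient_co2_ppm = ambient_co2_ppm, pressure_atm = pressure_atm,
         pressure_sd = pressure_sd, wind_meanlog = wind_meanlog,
         wind_sdlog = wind_sdlog, light_max = light_max,
         nee_intercept = nee_intercept, nee_light_coef = nee_light_coef,
         nee_sd = nee_sd, max_biomass = max_biomass,
         drop_series = as.integer(drop_series)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic chamber campaign configuration\n")
  cat("  lakes:", paste(sprintf("%s (x%g)", x$lakes, x$lake_multipliers),
                        collapse = ", "), "\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat(sprintf("  %d occasions %s to %s; %d/day (hourly on early days)\n",
              length(x$dates), format(min(x$dates)), format(max(x$dates)),
              x$enclosures_per_day))
  cat(sprintf("  log-flux: %.2f + %.3f * T(C) + log(lake mult); CV %.2f\n",
              x$baseline_log_flux, x$temp_coef, x$flux_cv))
  cat(sprintf("  noise %.3f ppm; ebullition p=%.3f jump %.1f ppm; seed %d\n",
              x$noise_sd_ppm, x$ebullition_prob, x$ebullition_jump_ppm,
              x$seed))
  invisible(x)
}

# Per-lake occasion schedule: dates, seasonal means, hourly flag
occasion_schedule <- function(config) {
  out <- vector("list", length(config$lakes))
  for (i in seq_along(config$lakes)) {
    if (i == 2 && config$lake2_skip_first && length(config$dates) > 1) {
      d <- config$dates[-1] + 1
      st <- config$seasonal_temp_c[-1]
    } else {
      d <- config$dates
      st <- config$seasonal_temp_c
    }
    out[[i]] <- data.frame(lake = config$lakes[i], date = d,
                           seasonal_temp_c = st,
                           occasion = seq_along(d),
                           hourly = seq_along(d) <= config$hourly_occasions[i])
  }
  do.call(rbind, out)
}

#' Simulate the environmental drivers of a campaign
#'
#' One record per (lake, date, clock time) slot.  Air temperature is the
#' occasion's seasonal mean plus a sinusoidal diel cycle peaking at 15:00
#' plus Gaussian noise; chamber temperature tracks air temperature closely
#' and relative humidity is strongly (negatively) coupled to it, so both
#' reproduce the collinearity that the screening step must catch.  Light is
#' exactly zero at night and follows a half-sine with log-normal cloudiness
#' by day; wind is log-normal; pressure is near-constant.
#'
#' @param config A [sim_config()].
#' @param seed Seed to set before drawing (default the config seed; pass
#'   `NULL` to continue the current RNG stream).
#' @return Data frame keyed by (lake, date, clock_hours).
#' @export
simulate_environment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sched <- occasion_schedule(config)
  rows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    slots <- if (sched$hourly[i]) 24L else config$enclosures_per_day
    h <- seq(0, 24 - 24 / slots, by = 24 / slots)
    n <- length(h)
    air <- sched$seasonal_temp_c[i] +
      config$diel_temp_amplitude * cos(2 * pi * (h - 15) / 24) +
      stats::rnorm(n, 0, config$temp_noise_sd)
    chamb <- air + stats::rnorm(n, 0, 0.5)
    hum <- pmin(100, pmax(20, 97 - 1.6 * air + stats::rnorm(n, 0, 3)))
    pres <- config$pressure_atm + stats::rnorm(n, 0, config$pressure_sd)
    wind <- stats::rlnorm(n, config$wind_meanlog, config$wind_sdlog)
    clear <- ifelse(h > 6 & h < 18,
                    config$light_max * sin(pi * (h - 6) / 12), 0)
    light <- clear * exp(stats::rnorm(n, 0, 0.3))
    rows[[i]] <- data.frame(lake = sched$lake[i], date = sched$date[i],
                            occasion = sched$occasion[i], clock_hours = h,
                            seasonal_temp_c = sched$seasonal_temp_c[i],
                            air_temp_c = air, chamber_temp_c = chamb,
                            humidity = hum, pressure_atm = pres, wind = wind,
                            light = light)
  }
  do.call(rbind, rows)
}

#' Draw ground-truth fluxes for a set of enclosures
#'
#' `log(true flux) = baseline + temp_coef * air temperature +
#' log(lake multiplier) + species offset`, optionally modulated by a diel
#' factor `1 + a * cos(2*pi*(h - 15)/24)`, times Gamma multiplicative noise
#' with mean 1 and CV `flux_cv`.  Ebullition indicators are Bernoulli with
#' the configured probability.  True NEE is drawn from the light-dependent
#' model in the config.
#'
#' @param enclosures Data frame with `lake`, `species`, `air_temp_c`,
#'   `clock_hours`, `light`.
#' @param config A [sim_config()].
#' @param seed As in [simulate_environment()].
#' @return Data frame with `true_flux_mmol_m2_d` (positive),
#'   `true_nee_mmol_m2_d`, `ebullition`; the generating coefficients are
#'   attached as attribute `"coefficients"`.
#' @export
simulate_true_flux <- function(enclosures, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(enclosures)
  mult <- config$lake_multipliers[match(enclosures$lake, config$lakes)]
  if (anyNA(mult)) {
    stop("configuration error: enclosure lake not present in config",
         call. = FALSE)
  }
  sp_off <- ifelse(enclosures$species == config$species[1],
                   config$species_offset, 0)
  lf <- config$baseline_log_flux + config$temp_coef * enclosures$air_temp_c +
    log(mult) + sp_off
  diel <- 1 + config$diel_flux_amplitude *
    cos(2 * pi * (enclosures$clock_hours - 15) / 24)
  eps <- if (config$flux_cv > 0) {
    shp <- 1 / config$flux_cv^2
    stats::rgamma(n, shape = shp, rate = shp)
  } else {
    rep(1, n)
  }
  flux <- exp(lf) * diel * eps
  ebul <- stats::runif(n) < config$ebullition_prob
  nee <- config$nee_intercept + config$nee_light_coef * enclosures$light +
    stats::rnorm(n, 0, config$nee_sd)
  out <- data.frame(true_flux_mmol_m2_d = flux, true_nee_mmol_m2_d = nee,
                    ebullition = ebul)
  if (!is.null(enclosures$enclosure_id)) {
    out <- cbind(data.frame(enclosure_id = enclosures$enclosure_id), out)
  }
  attr(out, "coefficients") <-
    list(baseline_log_flux = config$baseline_log_flux,
         temp_coef = config$temp_coef,
         lake_multipliers = config$lake_multipliers,
         species_offset = config$species_offset,
         diel_flux_amplitude = config$diel_flux_amplitude,
         flux_cv = config$flux_cv)
  out
}

#' Simulate one enclosure's analyser log
#'
#' Lays down the concentration ramp whose slope, run back through
#' [compute_flux()], returns exactly `true_flux` (the ideal-gas conversion
#' is inverted with [flux_to_slope()]), adds homoscedastic Gaussian analyser
#' noise, and — if `ebullition` — a single instantaneous step of
#' `jump_ppm` at a time drawn uniformly from the sample times after the
#' discard period.  (A bubble during the discarded mixing minute would shift
#' all retained samples equally and be absorbed by the regression intercept,
#' so it is unobservable by construction.)  The CO2 channel is generated the
#' same way from a signed NEE flux.
#'
#' @param true_flux CH4 flux to encode (mmol m-2 d-1, positive).
#' @param spec A [chamber_spec()].
#' @param temp_c,pressure_atm Conditions used for the ideal-gas inversion.
#' @param noise_sd_ppm,co2_noise_sd_ppm Per-sample Gaussian noise (ppm).
#' @param ebullition Inject a step jump?
#' @param jump_ppm Step size (ppm).
#' @param nee_flux CO2 flux to encode (mmol m-2 d-1, may be negative).
#' @param ambient_ch4_ppm,ambient_co2_ppm Concentrations at closure.
#' @param seed Optional seed (`NULL` continues the current stream).
#' @return Data frame `t_s`, `ch4_ppm`, `co2_ppm`.
#' @export
simulate_chamber_series <- function(true_flux, spec = chamber_spec(),
                                    temp_c = 15, pressure_atm = 0.99,
                                    noise_sd_ppm = 0, ebullition = FALSE,
                                    jump_ppm = 5, nee_flux = 0,
                                    co2_noise_sd_ppm = 0,
                                    ambient_ch4_ppm = 1.9,
                                    ambient_co2_ppm = 410, seed = NULL) {
  if (!is.finite(true_flux) || true_flux <= 0) {
    stop("domain error: true_flux must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  t_s <- seq(0, spec$duration_s, by = spec$interval_s)
  temp_k <- temp_c + 273.15
  sl <- flux_to_slope(true_flux, pressure_atm, temp_k, spec)
  ch4 <- ambient_ch4_ppm + sl * t_s / 86400 +
    stats::rnorm(length(t_s), 0, noise_sd_ppm)
  if (ebullition) {
    cand <- t_s[t_s > spec$discard_s]
    tj <- cand[sample.int(length(cand), 1L)]
    ch4[t_s >= tj] <- ch4[t_s >= tj] + jump_ppm
  }
  slc <- flux_to_slope(abs(nee_flux), pressure_atm, temp_k, spec) *
    sign(nee_flux)
  co2 <- ambient_co2_ppm + slc * t_s / 86400 +
    stats::rnorm(length(t_s), 0, co2_noise_sd_ppm)
  data.frame(t_s = t_s, ch4_ppm = ch4, co2_ppm = co2)
}

#' Simulate a complete chamber campaign with known ground truth
#'
#' Runs the full generative chain: environment ([simulate_environment()]),
#' site biomass trajectories (a seasonal bump peaking in August scaled to
#' the configured species-by-lake maxima), ground-truth fluxes
#' ([simulate_true_flux()]), and one analyser log per enclosure
#' ([simulate_chamber_series()]).  Optionally removes `drop_series` whole
#' daily series at random, mimicking field losses (default config: 26
#' site-days generated, 25 kept).  Fully deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `"chamber_study"`: list with data frames
#'   `enclosures` (metadata incl. weather and biomass), `gas_log` (long:
#'   enclosure_id, t_s, ch4_ppm, co2_ppm), `truth` (true flux, true NEE,
#'   ebullition indicator), `env`, and the `config`.
#' @export
simulate_chamber_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  env <- simulate_environment(config, seed = NULL)

  # one site per species per lake; both sites share a day's weather records
  enc <- do.call(rbind, lapply(config$species, function(sp) {
    x <- env
    x$species <- sp
    x
  }))
  enc$site <- paste(enc$lake, enc$species, sep = " / ")
  enc <- enc[order(enc$lake, enc$date, enc$clock_hours, enc$species), ]
  rownames(enc) <- NULL

  # seasonal biomass per site-day: bump peaking around day-of-year 222
  key <- unique(enc[c("lake", "species", "date")])
  doy <- as.integer(format(key$date, "%j"))
  shape <- 0.25 + 0.75 * exp(-((doy - 222) / 50)^2)
  peak <- config$max_biomass[cbind(match(key$species, config$species),
                                   match(key$lake, config$lakes))]
  key$biomass_gdw_m2 <- peak * shape * exp(stats::rnorm(nrow(key), 0, 0.1))
  enc <- merge(enc, key, by = c("lake", "species", "date"), sort = FALSE)
  enc <- enc[order(enc$lake, enc$date, enc$clock_hours, enc$species), ]
  rownames(enc) <- NULL
  enc$enclosure_id <- sprintf("E%04d", seq_len(nrow(enc)))

  truth <- simulate_true_flux(enc, config, seed = NULL)

  logs <- vector("list", nrow(enc))
  for (i in seq_len(nrow(enc))) {
    g <- simulate_chamber_series(
      truth$true_flux_mmol_m2_d[i], spec = config$chamber,
      temp_c = enc$air_temp_c[i], pressure_atm = enc$pressure_atm[i],
      noise_sd_ppm = config$noise_sd_ppm,
      ebullition = truth$ebullition[i],
      jump_ppm = config$ebullition_jump_ppm,
      nee_flux = truth$true_nee_mmol_m2_d[i],
      co2_noise_sd_ppm = config$co2_noise_sd_ppm,
      ambient_ch4_ppm = config$ambient_ch4_ppm,
      ambient_co2_ppm = config$ambient_co2_ppm, seed = NULL)
    g$enclosure_id <- enc$enclosure_id[i]
    logs[[i]] <- g[c("enclosure_id", "t_s", "ch4_ppm", "co2_ppm")]
  }
  gas <- do.call(rbind, logs)
  rownames(gas) <- NULL

  if (config$drop_series > 0) {
    series <- unique(enc[c("lake", "species", "date")])
    k <- min(config$drop_series, nrow(series) - 1L)
    drop <- series[sample.int(nrow(series), k), , drop = FALSE]
    tag <- function(d) paste(d$lake, d$species, d$date)
    keep <- !(tag(enc) %in% tag(drop))
    ids <- enc$enclosure_id[keep]
    enc <- enc[keep, ]
    truth <- truth[truth$enclosure_id %in% ids, ]
    gas <- gas[gas$enclosure_id %in% ids, ]
    rownames(enc) <- rownames(truth) <- rownames(gas) <- NULL
  }

  structure(list(enclosures = enc, gas_log = gas, truth = truth, env = env,
                 config = config),
            class = "chamber_study")
}

#' @export
print.chamber_study <- function(x, ...) {
  ser <- unique(x$enclosures[c("lake", "species", "date")])
  cat("Synthetic chamber study\n")
  cat(sprintf("  %d enclosures in %d daily series (%d lakes, %d species)\n",
              nrow(x$enclosures), nrow(ser), length(unique(ser$lake)),
              length(unique(ser$species))))
  cat(sprintf("  %d gas-log records; %d ebullition events injected; seed %d\n",
              nrow(x$gas_log), sum(x$truth$ebullition), x$config$seed))
  invisible(x)
}
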