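# --- plain-text dataset interchange ------------------------------------

# write a data frame as CSV with 17 significant digits so doubles
# round-trip exactly through the text representation
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (inherits(out[[j]], "Date")) {
      out[[j]] <- format(out[[j]])
    } else if (is.double(out[[j]])) {
      out[[j]] <- sprintf("%.17g", out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$dates <- format(x$dates)
  x$chamber <- unclass(x$chamber)
  x$lake_multipliers <- as.numeric(x$lake_multipliers)
  x$max_biomass <- list(values = as.numeric(x$max_biomass),
                        nrow = nrow(x$max_biomass))
  x
}

list_to_config <- function(x) {
  sim_config(seed = x$seed, lakes = x$lakes,
             lake_multipliers = x$lake_multipliers, species = x$species,
             dates = as.Date(x$dates), seasonal_temp_c = x$seasonal_temp_c,
             lake2_skip_first = x$lake2_skip_first,
             hourly_occasions = x$hourly_occasions,
             enclosures_per_day = x$enclosures_per_day,
             chamber = do.call(chamber_spec, x$chamber),
             baseline_log_flux = x$baseline_log_flux,
             temp_coef = x$temp_coef, species_offset = x$species_offset,
             flux_cv = x$flux_cv,
             diel_flux_amplitude = x$diel_flux_amplitude,
             diel_temp_amplitude = x$diel_temp_amplitude,
             temp_noise_sd = x$temp_noise_sd,
             noise_sd_ppm = x$noise_sd_ppm,
             co2_noise_sd_ppm = x$co2_noise_sd_ppm,
             ebullition_prob = x$ebullition_prob,
             ebullition_jump_ppm = x$ebullition_jump_ppm,
             ambient_ch4_ppm = x$ambient_ch4_ppm,
             ambient_co2_ppm = x$ambient_co2_ppm,
             pressure_atm = x$pressure_atm, pressure_sd = x$pressure_sd,
             wind_meanlog = x$wind_meanlog, wind_sdlog = x$wind_sdlog,
             light_max = x$light_max, nee_intercept = x$nee_intercept,
             nee_light_coef = x$nee_light_coef, nee_sd = x$nee_sd,
             max_biomass = matrix(x$max_biomass$values,
                                  nrow = x$max_biomass$nrow),
             drop_series = x$drop_series)
}

# small deterministic content hash (polynomial, mod 2^31 - 1) used to stamp
# outputs with the configuration they came from
config_hash <- function(obj) {
  s <- yaml::as.yaml(obj, precision = 17)
  b <- utf8ToInt(s)
  h <- 0
  for (chunk in split(b, ceiling(seq_along(b) / 4096))) {
    h <- Reduce(function(acc, x) (acc * 31 + x) %% 2147483647, chunk, h)
  }
  sprintf("%08x", as.integer(h))
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Writes `enclosures.csv`, `gas_log.csv`, `truth.csv`, `env.csv` and a
#' `config.yaml` manifest (configuration incl. seed).  Numeric columns are
#' written with 17 significant digits so a read-back reproduces the exact
#' doubles, and regeneration from the same config is byte-identical.
#'
#' @param study A `"chamber_study"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(study, dir) {
  stopifnot(inherits(study, "chamber_study"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) {
    stop("I/O error: cannot create directory '", dir, "'", call. = FALSE)
  }
  write_csv_exact(study$enclosures, file.path(dir, "enclosures.csv"))
  write_csv_exact(study$gas_log, file.path(dir, "gas_log.csv"))
  write_csv_exact(study$truth, file.path(dir, "truth.csv"))
  write_csv_exact(study$env, file.path(dir, "env.csv"))
  yaml::write_yaml(config_to_list(study$config), file.path(dir, "config.yaml"),
                   precision = 17)
  invisible(dir)
}

#' Read back a study written by [write_dataset()]
#'
#' @param dir Directory holding the CSV files and `config.yaml`.
#' @return A `"chamber_study"`.
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("enclosures.csv", "gas_log.csv", "config.yaml"))
  if (!all(file.exists(need))) {
    stop("I/O error: '", dir, "' is missing ",
         paste(basename(need)[!file.exists(need)], collapse = ", "),
         call. = FALSE)
  }
  rd <- function(f) {
    if (!file.exists(file.path(dir, f))) return(NULL)
    x <- utils::read.csv(file.path(dir, f))
    if ("date" %in% names(x)) x$date <- as.Date(x$date)
    x
  }
  structure(list(enclosures = rd("enclosures.csv"),
                 gas_log = rd("gas_log.csv"),
                 truth = rd("truth.csv"),
                 env = rd("env.csv"),
                 config = list_to_config(yaml::read_yaml(
                   file.path(dir, "config.yaml")))),
            class = "chamber_study")
}

#' Read and validate analyser gas logs
#'
#' Reads a long-format gas log (CSV file, directory containing
#' `gas_log.csv`, or an already-loaded data frame) and splits it into one
#' series per enclosure.  Each series must have strictly increasing times
#' and positive concentrations; offending enclosures are rejected with a
#' warning naming them, the rest are kept (no silent row loss: rejected ids
#' are attached as attribute `"rejected"`).
#'
#' @param path CSV path, directory, or data frame with columns
#'   `enclosure_id`, `t_s`, `ch4_ppm` (and optionally `co2_ppm`).
#' @return Named list of per-enclosure data frames.
#' @export
read_gas_logs <- function(path) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    f <- if (dir.exists(path)) file.path(path, "gas_log.csv") else path
    if (!file.exists(f)) {
      stop("I/O error: '", f, "' not found", call. = FALSE)
    }
    utils::read.csv(f)
  }
  need <- c("enclosure_id", "t_s", "ch4_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty gas log", call. = FALSE)
    return(structure(list(), rejected = character(0)))
  }
  series <- split(df, df$enclosure_id)
  ok <- vapply(series, function(s) {
    all(diff(s$t_s) > 0) && all(is.finite(s$ch4_ppm)) &&
      all(s$ch4_ppm > 0) &&
      (!"co2_ppm" %in% names(s) || all(s$co2_ppm > 0))
  }, logical(1))
  if (any(!ok)) {
    warning("validation error: rejecting enclosure(s) with non-monotone ",
            "times or non-positive concentrations: ",
            paste(names(series)[!ok], collapse = ", "), call. = FALSE)
  }
  structure(series[ok], rejected = names(series)[!ok])
}

#' Run the whole chamber-to-conclusion pipeline
#'
#' Executes the full analysis chain on a synthetic study or a dataset
#' directory: per-enclosure flux estimation with ebullition screening
#' ([estimate_fluxes()]), diel agreement ICC ([diel_icc()]), daily
#' summaries and daily-mean regressions ([daily_summaries()],
#' [daily_regressions()]), thinning of hourly days ([thin_by_day()]), a
#' collinearity screen over the continuous drivers
#' ([collinearity_screen()] — chamber temperature and humidity are
#' expected casualties of their coupling to air temperature), and
#' all-subsets Gamma GLZ model averaging ([flux_model_average()]).  Row
#' counts are tracked at every stage; outputs written to `out_dir` carry
#' the seed and a configuration hash in `manifest.yaml`.
#'
#' @param input A `"chamber_study"` or a directory written by
#'   [write_dataset()].
#' @param out_dir Optional output directory for the stage CSVs.
#' @param spec A [chamber_spec()] (defaults to the study's own chamber).
#' @param ebullition_k,r2_min Detector knobs.
#' @param n_classes,icc_variant Diel ICC options.
#' @param average,ic Model-averaging options.
#' @return Object of class `"pipeline_result"` with the stage outputs and
#'   counts.
#' @export
run_pipeline <- function(input, out_dir = NULL, spec = NULL,
                         ebullition_k = 10, r2_min = 0.9, n_classes = 10L,
                         icc_variant = "single", average = "full",
                         ic = "AIC") {
  study <- if (inherits(input, "chamber_study")) input else read_dataset(input)
  if (is.null(study$enclosures) || nrow(study$enclosures) == 0) {
    stop("analysis error (stage: read): no enclosures to process",
         call. = FALSE)
  }
  if (is.null(spec)) {
    spec <- if (!is.null(study$config)) study$config$chamber else chamber_spec()
  }
  fluxes <- estimate_fluxes(study, spec = spec, ebullition_k = ebullition_k,
                            r2_min = r2_min)
  n_read <- nrow(fluxes)
  clean <- fluxes[!fluxes$ebullition, ]
  n_excluded <- n_read - nrow(clean)

  icc <- diel_icc(clean, n_classes = n_classes, variant = icc_variant)
  daily <- daily_summaries(clean)
  regs <- daily_regressions(daily)

  thinned <- thin_by_day(clean)
  # the Gamma model requires a positive response; at very low fluxes the
  # analyser noise can push an estimate to or below zero — count and drop
  positive <- thinned$ch4_flux_mmol_m2_d > 0
  n_nonpositive <- sum(!positive)
  thinned <- thinned[positive, ]
  n_thinned <- nrow(thinned)

  cont <- intersect(c("air_temp_c", "chamber_temp_c", "humidity", "light",
                      "pressure_atm", "wind", "biomass_gdw_m2",
                      "co2_flux_mmol_m2_d"), names(thinned))
  screen <- collinearity_screen(thinned[cont])
  avg <- flux_model_average(
    thinned,
    terms = c(intersect(c("lake", "species"), names(thinned)),
              screen$retained),
    average = average, ic = ic)

  counts <- c(enclosures_read = n_read, ebullition_excluded = n_excluded,
              nonpositive_excluded = n_nonpositive, modeled = n_thinned)
  result <- structure(
    list(fluxes = fluxes, icc = icc, daily = daily, regressions = regs,
         screen = screen, averaged = avg, counts = counts,
         seed = if (!is.null(study$config)) study$config$seed else NA),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                            showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("I/O error: cannot create '", out_dir, "'", call. = FALSE)
    }
    write_csv_exact(fluxes, file.path(out_dir, "fluxes.csv"))
    write_csv_exact(daily, file.path(out_dir, "daily_summaries.csv"))
    write_csv_exact(regs, file.path(out_dir, "daily_regressions.csv"))
    write_csv_exact(
      data.frame(variant = icc$variant, coefficient = icc$coefficient,
                 icc_single = icc$icc_single, icc_average = icc$icc_average,
                 n_series = icc$n_series, k_classes = icc$k_classes,
                 f = icc$f, p_value = icc$p_value),
      file.path(out_dir, "diel_icc.csv"))
    write_csv_exact(avg$candidates, file.path(out_dir, "candidates.csv"))
    write_csv_exact(avg$coefficients, file.path(out_dir, "averaged.csv"))
    manifest <- list(
      seed = result$seed,
      config_hash = if (!is.null(study$config)) {
        config_hash(config_to_list(study$config))
      } else {
        NA
      },
      counts = as.list(counts),
      options = list(ebullition_k = ebullition_k, r2_min = r2_min,
                     n_classes = n_classes, icc_variant = icc_variant,
                     average = average, ic = ic))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Chamber flux pipeline result\n")
  cat(sprintf("  enclosures: %d read, %d excluded as ebullition, %d modeled\n",
              x$counts["enclosures_read"], x$counts["ebullition_excluded"],
              x$counts["modeled"]))
  cat(sprintf("  diel ICC (%s): %.3f (P = %.3g)\n", x$icc$variant,
              x$icc$coefficient, x$icc$p_value))
  best <- x$regressions[which.min(x$regressions$p_value), ]
  cat(sprintf("  strongest daily-mean regression: %s (slope %.3f, P = %.3g, adj R2 = %.2f)\n",
              best$driver, best$slope, best$p_value, best$adj_r_squared))
  if (nrow(x$screen$dropped)) {
    cat("  collinearity screen dropped:",
        paste(x$screen$dropped$variable, collapse = ", "), "\n")
  }
  cat(sprintf("  model averaging: %d candidates over %d observations\n",
              x$averaged$n_models, x$averaged$n))
  invisible(x)
}
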