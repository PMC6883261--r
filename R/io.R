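#' Read a daily weather CSV
#'
#' Expects the AZMET-like layout `date, solar_rad_ly, t_min_c, t_max_c,
#' precip_mm` with ISO-8601 dates; extra columns are ignored. Rows with an
#' unparseable date, a missing value or negative radiation are dropped with
#' a message naming their line numbers.
#'
#' @param path Path to the CSV file.
#' @return Data frame of validated daily records.
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "solar_rad_ly", "t_min_c", "t_max_c", "precip_mm")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("weather CSV is missing columns: ", paste(miss, collapse = ", "))
  date <- suppressWarnings(as.Date(raw$date))
  num <- raw[c("solar_rad_ly", "t_min_c", "t_max_c", "precip_mm")]
  bad <- is.na(date) | Reduce(`|`, lapply(num, is.na)) |
    raw$solar_rad_ly < 0 | raw$precip_mm < 0
  bad[is.na(bad)] <- TRUE
  if (any(bad))
    message("dropping ", sum(bad), " invalid weather row(s) at line(s): ",
            paste(which(bad) + 1, collapse = ", "))
  out <- data.frame(date = date, solar_rad_ly = raw$solar_rad_ly,
                    t_min_c = raw$t_min_c, t_max_c = raw$t_max_c,
                    precip_mm = raw$precip_mm)[!bad, ]
  rownames(out) <- NULL
  out
}

#' Write a daily weather CSV
#'
#' Counterpart of [read_weather_csv()]; writes at full float precision so
#' round-trips are lossless.
#'
#' @param weather Data frame of daily records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  df <- weather
  df$date <- format(as.Date(df$date), "%Y-%m-%d")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 24 h flux-trace CSV
#'
#' Expects columns `elapsed_s, assim_umol_m2_s, light_on`.
#'
#' @param path Path to the CSV file.
#' @return A [flux_trace()].
#' @export
read_flux_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("elapsed_s", "assim_umol_m2_s", "light_on")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("trace CSV is missing columns: ", paste(miss, collapse = ", "))
  flux_trace(raw$elapsed_s, raw$assim_umol_m2_s, as.logical(raw$light_on))
}

#' Write a flux trace as CSV
#' @param trace A [flux_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "flux_trace"))
  df <- data.frame(elapsed_s = format(trace$times, digits = 17, trim = TRUE),
                   assim_umol_m2_s = format(trace$assimilation, digits = 17,
                                            trim = TRUE),
                   light_on = trace$light_on)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a monthly climate CSV
#'
#' Expects columns `year, month, mean_daily_par, total_moisture_mm,
#' t_min_night_c, t_max_day_c` (the last optional).
#'
#' @param path Path to the CSV file.
#' @return Data frame of monthly climate summaries.
#' @export
read_monthly_climate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "month", "mean_daily_par", "total_moisture_mm",
            "t_min_night_c")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("climate CSV is missing columns: ", paste(miss, collapse = ", "))
  raw
}

#' Assemble a pipeline configuration
#'
#' Bundles every mode switch and coefficient the monthly pipeline uses, with
#' the published model coefficients as defaults. Flags such as the light and
#' temperature modes select between the published (rounded) curves and
#' their internally consistent variants; see [light_index()],
#' [temperature_index()] and [agave_yield_models()].
#'
#' @param weather_csv Path to a daily weather CSV (or `NULL` if a climate
#'   table is supplied directly to [run_pipeline()]).
#' @param latitude Site latitude, degrees.
#' @param irrigation_total_mm Annual irrigation to schedule with
#'   [irrigation_schedule()], or a 12-vector of monthly depths.
#' @param light_mode,temp_mode Index mode switches.
#' @param biomass_variant `"printed"` or `"corrected"` biomass slope.
#' @param epi_from,epi_to Optional `"YYYY-MM"` cumulative-EPI window.
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(weather_csv = NULL, latitude = 33,
                            irrigation_total_mm = 0,
                            light_mode = c("normalized", "printed"),
                            temp_mode = c("acidity_scaled", "printed"),
                            biomass_variant = c("printed", "corrected"),
                            epi_from = NULL, epi_to = NULL, seed = 1) {
  structure(list(weather_csv = weather_csv,
                 latitude = latitude,
                 irrigation_total_mm = irrigation_total_mm,
                 light_mode = match.arg(light_mode),
                 temp_mode = match.arg(temp_mode),
                 biomass_variant = match.arg(biomass_variant),
                 epi_from = epi_from, epi_to = epi_to, seed = seed),
            class = "pipeline_config")
}

#' Run the monthly EPI pipeline
#'
#' Executes the full chain: read (or accept) daily weather, aggregate to
#' monthly climate, compute the three indices and monthly EPI, accumulate
#' EPI over the configured window, and predict biomass and combustible
#' energy yields. Outputs are deterministic given the inputs and config;
#' when `out_dir` is given, per-month tables, predictions and a run log
#' recording every mode and coefficient choice are written there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if absent).
#' @param climate Optional pre-built monthly climate table overriding
#'   `config$weather_csv`.
#' @return List with `climate`, `epi_table` (indices and monthly EPI),
#'   `epi_sum`, `biomass_mg_ha`, `energy_mj_ha`.
#' @export
run_pipeline <- function(config, out_dir = NULL, climate = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(climate)) {
    if (is.null(config$weather_csv))
      stop("pipeline: supply `climate` or set `weather_csv` in the config")
    daily <- read_weather_csv(config$weather_csv)
    climate <- aggregate_monthly(daily, config$irrigation_total_mm,
                                 latitude = config$latitude)
  }
  idx <- monthly_indices(climate, light_mode = config$light_mode,
                         temp_mode = config$temp_mode)
  idx$epi <- monthly_epi(idx)
  epi_sum <- cumulative_epi(idx, config$epi_from, config$epi_to)
  models <- agave_yield_models()
  bm_model <- if (config$biomass_variant == "printed")
    models$biomass_printed else models$biomass_corrected
  biomass <- predict_biomass(epi_sum, bm_model)
  energy <- predict_energy(epi_sum, models$energy)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(idx, file.path(out_dir, "monthly_epi.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(epi_sum = epi_sum, biomass_mg_ha = biomass,
                 energy_mj_ha = energy),
      file.path(out_dir, "predictions.csv"), row.names = FALSE)
    writeLines(c(
      "agavepi pipeline run",
      paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      paste0("weather_csv: ", config$weather_csv %||% "<climate supplied>"),
      paste0("latitude: ", config$latitude),
      paste0("irrigation_total_mm: ",
             paste(config$irrigation_total_mm, collapse = " ")),
      paste0("light_mode: ", config$light_mode),
      paste0("temp_mode: ", config$temp_mode),
      paste0("biomass_variant: ", config$biomass_variant,
             " (slope ", bm_model$slope, ", intercept ",
             bm_model$intercept, ")"),
      paste0("energy model: slope ", models$energy$slope,
             ", intercept ", models$energy$intercept),
      paste0("epi_window: ", config$epi_from %||% "start", " .. ",
             config$epi_to %||% "end"),
      paste0("seed: ", config$seed),
      paste0("epi_sum: ", format(epi_sum, digits = 17)),
      paste0("biomass_mg_ha: ", format(biomass, digits = 17)),
      paste0("energy_mj_ha: ", format(energy, digits = 17))),
      file.path(out_dir, "run_log.txt"))
  }
  list(climate = climate, epi_table = idx, epi_sum = epi_sum,
       biomass_mg_ha = biomass, energy_mj_ha = energy)
}

#' Read a pipeline config from JSON
#'
#' @param path Path to a JSON file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
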