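#' Configure the synthetic weather generator
#'
#' Defaults describe a Sonoran-desert site at 33 degrees N (Maricopa-like):
#' daily solar radiation cycling 250--750 Langley around a 500 Langley mean
#' peaking at the summer solstice, night minima cycling 3--25 degC around
#' 14 degC lagging the solstice by about a month, a ~16 degC diurnal range,
#' and sparse monsoon-skewed precipitation totalling ~105 mm per year.
#'
#' @param latitude Site latitude, degrees.
#' @param radiation_mean,radiation_amplitude Annual mean and seasonal
#'   amplitude of daily solar radiation, Langley.
#' @param radiation_noise_sd Day-to-day Gaussian radiation noise, Langley
#'   (cloudiness); simulated radiation is floored at 0.
#' @param night_temp_mean,night_temp_amplitude Annual mean and seasonal
#'   amplitude of the daily minimum (night) temperature, degC.
#' @param temp_noise_sd Day-to-day Gaussian temperature noise, degC.
#' @param diurnal_range Mean excess of the daily maximum over the minimum,
#'   degC.
#' @param precip_monthly_means Expected precipitation totals per calendar
#'   month, mm (12 values).
#' @return A validated `weather_sim_config` list.
#' @export
weather_sim_config <- function(latitude = 33,
                               radiation_mean = 500,
                               radiation_amplitude = 250,
                               radiation_noise_sd = 60,
                               night_temp_mean = 14,
                               night_temp_amplitude = 11,
                               temp_noise_sd = 2,
                               diurnal_range = 16,
                               precip_monthly_means =
                                 c(8, 8, 8, 4, 2, 1, 18, 22, 12, 8, 6, 8)) {
  stopifnot(abs(latitude) <= 90,
            radiation_amplitude >= 0, night_temp_amplitude >= 0,
            radiation_noise_sd >= 0, temp_noise_sd >= 0,
            diurnal_range >= 0,
            length(precip_monthly_means) == 12,
            all(precip_monthly_means >= 0))
  structure(list(latitude = latitude,
                 radiation_mean = radiation_mean,
                 radiation_amplitude = radiation_amplitude,
                 radiation_noise_sd = radiation_noise_sd,
                 night_temp_mean = night_temp_mean,
                 night_temp_amplitude = night_temp_amplitude,
                 temp_noise_sd = temp_noise_sd,
                 diurnal_range = diurnal_range,
                 precip_monthly_means = precip_monthly_means),
            class = "weather_sim_config")
}

#' Simulate a daily weather series
#'
#' Generates daily solar radiation, min/max air temperature and
#' precipitation with sinusoidal seasonal cycles plus seeded Gaussian noise.
#' Radiation peaks at the summer solstice (day 172), temperature about a
#' month later (day 202). Precipitation falls on sparse wet days
#' (Bernoulli) with exponentially distributed depths whose expectation
#' matches the configured monthly means. Identical seeds give identical
#' series; the caller's RNG state is untouched.
#'
#' @param config A [weather_sim_config()].
#' @param start_date,end_date Inclusive date range (`Date` or ISO-8601
#'   strings).
#' @param seed Integer seed.
#' @return Data frame with columns `date`, `solar_rad_ly`, `t_min_c`,
#'   `t_max_c`, `precip_mm`.
#' @export
#' @examples
#' w <- simulate_daily_weather(weather_sim_config(), "2012-04-01",
#'                             "2012-04-30", seed = 1)
simulate_daily_weather <- function(config, start_date, end_date, seed = 1) {
  stopifnot(inherits(config, "weather_sim_config"))
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (end_date < start_date) stop("empty date range")
  dates <- seq(start_date, end_date, by = "day")
  doy <- as.integer(format(dates, "%j"))
  mon <- as.integer(format(dates, "%m"))
  n <- length(dates)
  with_seed(seed, {
    season_rad <- cos(2 * pi * (doy - 172) / 365.25)
    rad <- config$radiation_mean + config$radiation_amplitude * season_rad +
      stats::rnorm(n, 0, config$radiation_noise_sd)
    rad <- pmax(0, rad)
    season_t <- cos(2 * pi * (doy - 202) / 365.25)
    tmin <- config$night_temp_mean +
      config$night_temp_amplitude * season_t +
      stats::rnorm(n, 0, config$temp_noise_sd)
    tmax <- tmin + config$diurnal_range +
      abs(stats::rnorm(n, 0, config$temp_noise_sd))
    # wet-day probability scaled to the monthly mean; depth exponential
    mdays <- vapply(seq_len(n), function(i)
      days_in_month(as.integer(format(dates[i], "%Y")), mon[i]), integer(1))
    mu <- config$precip_monthly_means[mon]
    p_wet <- pmin(0.5, mu / 60)
    wet <- stats::runif(n) < p_wet
    depth <- ifelse(p_wet > 0, mu / (mdays * p_wet), 0)
    precip <- ifelse(wet, stats::rexp(n, rate = 1) * depth, 0)
    data.frame(date = dates, solar_rad_ly = rad, t_min_c = tmin,
               t_max_c = tmax, precip_mm = precip)
  })
}

#' Build a seasonal irrigation schedule
#'
#' Emulates a grower applying a roughly fixed monthly depth (default 75 mm)
#' over a season whose length grows with the annual allocation, centred on
#' midsummer: the months enter in the order Jun, Jul, Aug, Sep, May, Oct,
#' Apr, Mar, Nov, Feb, Dec, Jan. 300 mm thus irrigates Jun--Sep, 460 mm
#' May--Oct and 530 mm Apr--Oct. Schedules for larger allocations nest
#' those for smaller ones, so cumulative EPI is monotone in the annual
#' total.
#'
#' @param annual_total Annual irrigation, mm, `>= 0`.
#' @param event_depth Target monthly application depth, mm.
#' @return Numeric vector of 12 monthly irrigation depths (mm) summing to
#'   `annual_total`.
#' @export
#' @examples
#' irrigation_schedule(530)
irrigation_schedule <- function(annual_total, event_depth = 75) {
  stopifnot(annual_total >= 0, event_depth > 0)
  sched <- numeric(12)
  if (annual_total == 0) return(sched)
  order <- c(6, 7, 8, 9, 5, 10, 4, 3, 11, 2, 12, 1)
  n <- min(12, max(1, round(annual_total / event_depth)))
  sched[order[seq_len(n)]] <- annual_total / n
  sched
}

#' Aggregate daily weather to monthly climate summaries
#'
#' Collapses a daily series to the monthly quantities the index functions
#' consume: mean daytime PAR (monthly mean daily radiation divided by the
#' month's astronomical mean day length, converted with
#' [mean_par_from_daily_radiation()]), total moisture (summed precipitation
#' plus the scheduled irrigation), and means of the daily minima and maxima.
#' Partial months are refused: a truncated month would bias every mean.
#'
#' @param daily Data frame as returned by [simulate_daily_weather()] or
#'   [read_weather_csv()].
#' @param irrigation Numeric vector of 12 monthly irrigation depths (mm),
#'   e.g. from [irrigation_schedule()], or a single annual total to be
#'   scheduled with defaults.
#' @param latitude Site latitude for day-length computation.
#' @param daylight_hours Optional numeric vector of 12 user-supplied monthly
#'   mean day lengths (hours), overriding the astronomical computation so a
#'   station workflow can be mirrored exactly.
#' @return Data frame with columns `year`, `month`, `mean_daily_par`,
#'   `total_moisture_mm`, `t_min_night_c`, `t_max_day_c`.
#' @export
aggregate_monthly <- function(daily, irrigation = numeric(12), latitude = 33,
                              daylight_hours = NULL) {
  need <- c("date", "solar_rad_ly", "t_min_c", "t_max_c", "precip_mm")
  miss <- setdiff(need, names(daily))
  if (length(miss))
    stop("`daily` is missing columns: ", paste(miss, collapse = ", "))
  if (length(irrigation) == 1) irrigation <- irrigation_schedule(irrigation)
  stopifnot(length(irrigation) == 12)
  if (!is.null(daylight_hours)) stopifnot(length(daylight_hours) == 12)
  d <- daily[order(daily$date), ]
  yr <- as.integer(format(d$date, "%Y"))
  mo <- as.integer(format(d$date, "%m"))
  key <- yr * 100 + mo
  out <- do.call(rbind, lapply(unique(key), function(k) {
    sel <- key == k
    y <- k %/% 100; m <- k %% 100
    if (sum(sel) != days_in_month(y, m))
      stop(sprintf("month %d-%02d is incomplete (%d of %d days)",
                   y, m, sum(sel), days_in_month(y, m)))
    dl <- if (is.null(daylight_hours))
      monthly_mean_daylight_hours(latitude, m, y) else daylight_hours[m]
    data.frame(
      year = y, month = m,
      mean_daily_par = mean_par_from_daily_radiation(
        mean(d$solar_rad_ly[sel]), dl),
      total_moisture_mm = sum(d$precip_mm[sel]) + irrigation[m],
      t_min_night_c = mean(d$t_min_c[sel]),
      t_max_day_c = mean(d$t_max_c[sel]))
  }))
  rownames(out) <- NULL
  out
}

#' Configure a synthetic CAM flux trace
#'
#' @param ppfd Acclimation PPFD, umol m^-2 s^-1, `>= 0`.
#' @param photoperiod Light period, hours (default 12, the growth-chamber
#'   regime).
#' @param noise_sd Gaussian instrument noise on each sample,
#'   umol m^-2 s^-1.
#' @param sample_interval Sampling interval, seconds (default 300 -- 5 min
#'   logging).
#' @return A validated `cam_trace_config` list.
#' @export
cam_trace_config <- function(ppfd, photoperiod = 12, noise_sd = 0.1,
                             sample_interval = 300) {
  stopifnot(ppfd >= 0, photoperiod > 0, photoperiod < 24,
            noise_sd >= 0, sample_interval > 0)
  structure(list(ppfd = ppfd, photoperiod = photoperiod,
                 noise_sd = noise_sd, sample_interval = sample_interval),
            class = "cam_trace_config")
}

#' Simulate a four-phase CAM diel flux trace
#'
#' Builds a 24 h net CO2 assimilation trace with the canonical obligate-CAM
#' shape: a nocturnal uptake plateau (phase 1), no dawn spike (phase 2 --
#' not observed in A. americana), a slightly negative daytime flux behind
#' closed stomata (phase 3), and a dusk spike (phase 4) that is suppressed
#' at PPFD <= 100 umol m^-2 s^-1, where only dark-period assimilation
#' occurs. Phase transitions are 30 min linear ramps to avoid integrator
#' artifacts. The trace starts at lights-on.
#'
#' The nocturnal amplitude is solved so that the noiseless trace's Simpson
#' integral equals the fitted quadratic light response evaluated at the
#' configured PPFD; the generator therefore has a known true 24 h integral.
#' At very low PPFD the target is negative and the nocturnal plateau
#' becomes a small efflux, reproducing the observed net-negative traces.
#'
#' @param config A [cam_trace_config()].
#' @param seed Integer seed for the additive noise.
#' @return List with elements `trace` (a [flux_trace()]), `true_integral`
#'   (mol CO2 m^-2 per 24 h, the noiseless Simpson integral) and
#'   `amplitude` (nocturnal plateau height, umol m^-2 s^-1).
#' @export
#' @examples
#' sim <- simulate_cam_trace(cam_trace_config(1250, noise_sd = 0), seed = 1)
#' integrate_daily_net(sim$trace)  # = sim$true_integral = 0.6244
simulate_cam_trace <- function(config, seed = 1) {
  stopifnot(inherits(config, "cam_trace_config"))
  k <- epi_constants()
  times <- seq(0, 86400, by = config$sample_interval)
  day_s <- config$photoperiod * 3600
  light_on <- times < day_s
  ramp <- 1800  # 30 min transitions

  # piecewise-linear bump: 0 before t0, ramps to 1 over `ramp`, holds to
  # t1 - ramp, ramps back to 0 at t1
  bump <- function(t, t0, t1) {
    pmax(0, pmin(1, pmin((t - t0) / ramp, (t1 - t) / ramp)))
  }
  # scalable part: nocturnal plateau + dusk spike at 25% of the plateau
  u <- bump(times, day_s, 86400)
  spike_ratio <- if (config$ppfd > 100) 0.25 else 0
  u <- u + spike_ratio * bump(times, day_s - 5400, day_s)
  # fixed part: slight daytime efflux (phase 3)
  f <- -0.2 * bump(times, 0, day_s - 5400)

  target <- polyval_asc(k$assim_quadratic, config$ppfd)
  iu <- simpson_integral(times, u) * 1e-6
  iff <- simpson_integral(times, f) * 1e-6
  amp <- (target - iff) / iu
  clean <- amp * u + f
  noise <- with_seed(seed,
                     stats::rnorm(length(times), 0, config$noise_sd))
  list(trace = flux_trace(times, clean + noise, light_on),
       true_integral = target,
       amplitude = amp)
}

#' Simulate yield observations from a linear EPI law
#'
#' Draws `yield = slope * epi_sum + intercept + N(0, noise_sd)`, floored at
#' 0, for each supplied cumulative EPI value.
#'
#' @param model A [yield_model()].
#' @param epi_sums Cumulative EPI values.
#' @param noise_sd Gaussian noise standard deviation in yield units, `>= 0`.
#' @param seed Integer seed.
#' @return Data frame with columns `epi_sum` and `yield`.
#' @export
simulate_yield_dataset <- function(model, epi_sums, noise_sd = 0, seed = 1) {
  stopifnot(inherits(model, "yield_model"), noise_sd >= 0)
  y <- with_seed(seed, {
    model$slope * epi_sums + model$intercept +
      stats::rnorm(length(epi_sums), 0, noise_sd)
  })
  data.frame(epi_sum = epi_sums, yield = pmax(0, y))
}
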