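#' Monthly light index
#'
#' Fraction of maximum 24 h carbon gain attainable at a monthly mean PPFD,
#' on `[0, 1]`.
#'
#' Two modes are available. `"normalized"` (default) evaluates the fitted
#' assimilation quadratic divided by its vertex value (0.6244 mol d^-1), so
#' the index attains exactly 1 at the 1250 umol m^-2 s^-1 saturation point.
#' `"printed"` evaluates the published rounded index quadratic
#' `-7e-7 x^2 + 0.0016 x - 0.001`, whose rounding caps its maximum at
#' ~0.905; it is kept for auditability against published monthly series.
#' Both modes clamp to `[0, 1]`.
#'
#' @param ppfd Monthly mean daytime PPFD, umol m^-2 s^-1, `>= 0`. Vectorized.
#' @param mode `"normalized"` or `"printed"`.
#' @param fit Optional `light_response_fit` to normalize instead of the
#'   built-in assimilation quadratic (only used by `"normalized"`).
#' @return Index values in `[0, 1]`.
#' @export
#' @examples
#' light_index(1250)              # 1
#' light_index(1250, "printed")   # 0.90525
light_index <- function(ppfd, mode = c("normalized", "printed"), fit = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(ppfd))
  if (any(ppfd < 0, na.rm = TRUE)) stop("`ppfd` must be >= 0")
  k <- epi_constants()
  if (mode == "printed") {
    raw <- polyval_asc(k$light_index_quadratic, ppfd)
  } else {
    if (is.null(fit)) {
      q <- k$assim_quadratic
      fit <- light_response_fit(a = q[3], b = q[2], c = q[1])
    }
    curve <- derive_light_index_curve(fit)
    raw <- polyval_asc(c(curve$c, curve$b, curve$a), ppfd)
  }
  clamp01(raw)
}

#' Monthly water index
#'
#' Linear response of relative productivity to total monthly moisture
#' (precipitation plus irrigation): `0.0279 x - 0.2851`, clamped below at 0
#' and, because a linear response would otherwise exceed the optimum, capped
#' at 1.00 for any month receiving more than ~46.1 mm.
#'
#' @param total_moisture Total monthly water input, mm, `>= 0`. Vectorized.
#' @return Index values in `[0, 1]`.
#' @export
#' @examples
#' water_index(45)  # 0.9704
#' water_index(60)  # 1 (capped)
water_index <- function(total_moisture) {
  stopifnot(is.numeric(total_moisture))
  if (any(total_moisture < 0, na.rm = TRUE))
    stop("`total_moisture` must be >= 0")
  k <- epi_constants()
  clamp01(k$water_index_slope * total_moisture + k$water_index_intercept)
}

#' Leaf night temperature from air minimum
#'
#' A. americana leaf temperatures run about 2 degC above ambient night
#' minima; the temperature index is driven by leaf, not air, temperature.
#'
#' @param air_min_temp Monthly mean minimum air temperature, degC.
#' @return Leaf night temperature, degC (`air_min_temp + 2`).
#' @export
leaf_night_temperature <- function(air_min_temp) {
  stopifnot(is.numeric(air_min_temp))
  air_min_temp + epi_constants()$leaf_temp_offset
}

#' Titratable-acidity response to night temperature
#'
#' The fifth-order polynomial relating nocturnal titratable tissue acidity
#' (percent of maximum, a proxy for nocturnal CO2 fixation) to night
#' temperature in degC. Optimum near 15 degC; crosses zero on the cold side
#' near -3 degC. Returned un-clamped and un-gated -- see
#' [temperature_index()] for the index proper.
#'
#' @param temp Night temperature, degC. Vectorized.
#' @return Percent of maximum acidity (may fall outside `[0, 100]` away
#'   from the fitted range).
#' @export
#' @examples
#' titratable_acidity_response(15)  # ~99.5
titratable_acidity_response <- function(temp) {
  stopifnot(is.numeric(temp))
  polyval_asc(epi_constants()$acidity_quintic, temp)
}

#' Monthly temperature index
#'
#' Relative productivity as a function of leaf night temperature, on
#' `[0, 1]`.
#'
#' The default mode `"acidity_scaled"` evaluates the titratable-acidity
#' quintic divided by 100. The `"printed"` mode evaluates the published
#' index quintic verbatim; its leading coefficient (-0.2e-7) is a factor of
#' 10 smaller than the acidity quintic's scaled value (-2e-7) and the curve
#' consequently evaluates to ~15 at 38 degC -- an evident transcription
#' problem, so it is not the default. In both modes the index is forced to
#' 0 when productivity ceases (night temperature <= -3 degC or >= 38 degC)
#' and clamped to `[0, 1]` (the fitted polynomial slightly exceeds 1 over
#' ~22--36 degC).
#'
#' @param leaf_night_temp Leaf night temperature, degC
#'   (see [leaf_night_temperature()]). Vectorized.
#' @param mode `"acidity_scaled"` or `"printed"`.
#' @return Index values in `[0, 1]`.
#' @export
#' @examples
#' temperature_index(15)   # ~0.995, the optimum
#' temperature_index(-5)   # 0, below the cold cease threshold
temperature_index <- function(leaf_night_temp,
                              mode = c("acidity_scaled", "printed")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(leaf_night_temp))
  k <- epi_constants()
  raw <- if (mode == "acidity_scaled")
    titratable_acidity_response(leaf_night_temp) / 100
  else
    polyval_asc(k$temp_index_quintic, leaf_night_temp)
  raw[leaf_night_temp <= k$temp_cease_low |
        leaf_night_temp >= k$temp_cease_high] <- 0
  clamp01(raw)
}

#' Compute the three monthly indices for a climate series
#'
#' Applies [leaf_night_temperature()] and the three index functions to a
#' monthly climate table. Daytime maxima never modify an index (CO2
#' assimilation in A. americana is unaffected by daytime heat until about
#' 45 degC); months exceeding 45 degC only trigger a warning.
#'
#' @param climate Data frame with columns `year`, `month`, `mean_daily_par`
#'   (umol m^-2 s^-1), `total_moisture_mm`, `t_min_night_c` and optionally
#'   `t_max_day_c`.
#' @param light_mode,temp_mode Passed to [light_index()] and
#'   [temperature_index()].
#' @param fit Optional `light_response_fit` for the light index.
#' @return `climate` with columns `light`, `water`, `temperature` appended.
#' @export
monthly_indices <- function(climate,
                            light_mode = c("normalized", "printed"),
                            temp_mode = c("acidity_scaled", "printed"),
                            fit = NULL) {
  light_mode <- match.arg(light_mode)
  temp_mode <- match.arg(temp_mode)
  need <- c("year", "month", "mean_daily_par", "total_moisture_mm",
            "t_min_night_c")
  miss <- setdiff(need, names(climate))
  if (length(miss))
    stop("`climate` is missing columns: ", paste(miss, collapse = ", "))
  if (any(climate$t_min_night_c >
            climate$t_max_day_c %||% Inf, na.rm = TRUE))
    stop("night minimum temperatures exceed day maxima")
  if (!is.null(climate$t_max_day_c) &&
        any(climate$t_max_day_c > epi_constants()$daytime_temp_warn,
            na.rm = TRUE))
    warning("monthly maximum day temperature exceeds 45 degC; ",
            "the model assumes daytime heat does not limit assimilation")
  climate$light <- light_index(climate$mean_daily_par, light_mode, fit = fit)
  climate$water <- water_index(climate$total_moisture_mm)
  climate$temperature <- temperature_index(
    leaf_night_temperature(climate$t_min_night_c), temp_mode)
  climate
}

`%||%` <- function(a, b) if (is.null(a)) b else a
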