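#' Convert Langley to watt-hours per square metre
#'
#' Daily solar radiation totals from AZMET-style weather stations are
#' recorded in Langley (1 Langley = 41 868 J m^-2). The published conversion
#' to visible-spectrum energy, 11.622 Wh m^-2 per Langley, is applied
#' verbatim; the physically exact 41 868/3600 = 11.63 differs by <0.1% and
#' is available in [epi_constants()].
#'
#' @param radiation Daily solar radiation in Langley; numeric vector, `>= 0`.
#' @return Watt-hours per square metre, same length as `radiation`.
#' @export
#' @examples
#' langley_to_watt_hours(1)    # 11.622
#' langley_to_watt_hours(600)
langley_to_watt_hours <- function(radiation) {
  stopifnot(is.numeric(radiation))
  if (any(radiation < 0, na.rm = TRUE))
    stop("`radiation` must be >= 0 (Langley is a daily energy total)")
  radiation * epi_constants()$langley_to_wh
}

#' Astronomical day length
#'
#' Day length in hours from latitude and day of year, using the standard
#' solar-geometry approximation: declination
#' `delta = 23.44 * sin(2*pi*(284 + n)/365)` degrees and sunset hour angle
#' `H = acos(-tan(phi) tan(delta))`. The hour-angle cosine is clipped to
#' `[-1, 1]` so polar day/night yield 24 or 0 h rather than `NaN`.
#'
#' @param latitude Degrees, in `[-90, 90]`.
#' @param day_of_year Integer day of year, in `[1, 366]`. Vectorized; recycled
#'   against `latitude`.
#' @return Day length in hours, in `[0, 24]`.
#' @export
#' @examples
#' daylight_hours(0, 80)    # ~12 h at the equator near the equinox
#' daylight_hours(33, 172)  # midsummer at Sonoran-desert latitude
daylight_hours <- function(latitude, day_of_year) {
  stopifnot(is.numeric(latitude), is.numeric(day_of_year))
  if (any(abs(latitude) > 90))
    stop("`latitude` must lie in [-90, 90] degrees")
  if (any(day_of_year < 1 | day_of_year > 366))
    stop("`day_of_year` must lie in [1, 366]")
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- latitude * pi / 180
  cos_h <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  2 * acos(cos_h) * 180 / pi / 15
}

#' Monthly mean day length
#'
#' Arithmetic mean of [daylight_hours()] over every calendar day of a month,
#' with leap years handled by the actual month length. This supplies the
#' "average daylight hours for that month" used in the Langley-to-PAR chain
#' when no station-specific values are supplied.
#'
#' @param latitude Degrees, in `[-90, 90]`.
#' @param month Integer month, 1--12.
#' @param year Calendar year (used for leap-day handling).
#' @return Mean day length in hours.
#' @export
monthly_mean_daylight_hours <- function(latitude, month, year) {
  stopifnot(length(month) == 1, length(year) == 1)
  if (month < 1 || month > 12) stop("`month` must be in 1..12")
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  days <- seq(first, by = "day",
              length.out = days_in_month(year, month))
  doy <- as.integer(format(days, "%j"))
  mean(daylight_hours(latitude, doy))
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- if (month == 12) as.Date(sprintf("%d-01-01", year + 1)) else
    as.Date(sprintf("%d-%02d-01", year, month + 1))
  as.integer(nxt - first)
}

#' Mean daytime PAR from a daily radiation total
#'
#' Converts a daily solar radiation total (Langley) to the mean
#' photosynthetic photon flux density (PPFD) over the daylight period, via
#' the chain Langley -> Wh m^-2 (x 11.622) -> mean W m^-2 (/ daylight hours)
#' -> lux (x 110 lm W^-1) -> klux (/1000) -> PPFD (x 18 umol m^-2 s^-1 per
#' klux). The composite factor is 23.01156 umol m^-2 s^-1 per
#' Langley-per-daylight-hour.
#'
#' @param radiation Daily solar radiation, Langley, `>= 0`.
#' @param daylight Daylight hours over which the total accrued, `> 0`.
#' @return Mean PPFD in umol photons m^-2 s^-1.
#' @export
#' @examples
#' mean_par_from_daily_radiation(600, 12)  # 1150.58
mean_par_from_daily_radiation <- function(radiation, daylight) {
  stopifnot(is.numeric(radiation), is.numeric(daylight))
  if (any(radiation < 0, na.rm = TRUE)) stop("`radiation` must be >= 0")
  if (any(daylight <= 0, na.rm = TRUE)) stop("`daylight` must be > 0")
  radiation / daylight * epi_constants()$langley_per_hour_to_ppfd
}

#' Daily photon dose
#'
#' Integrated photon receipt over a photoperiod:
#' `ppfd * photoperiod * 3600 * 1e-6` mol photons m^-2 d^-1. At the light
#' saturation point of 1250 umol m^-2 s^-1 over a 12 h photoperiod this is
#' 54 mol photons m^-2 d^-1.
#'
#' @param ppfd Photosynthetic photon flux density, umol m^-2 s^-1, `>= 0`.
#' @param photoperiod Hours of light, in `[0, 24]`.
#' @return mol photons m^-2 d^-1.
#' @export
#' @examples
#' photon_dose(1250, 12)  # 54
photon_dose <- function(ppfd, photoperiod) {
  stopifnot(is.numeric(ppfd), is.numeric(photoperiod))
  if (any(ppfd < 0, na.rm = TRUE)) stop("`ppfd` must be >= 0")
  if (any(photoperiod < 0 | photoperiod > 24, na.rm = TRUE))
    stop("`photoperiod` must lie in [0, 24] hours")
  ppfd * photoperiod * 3600 * 1e-6
}
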