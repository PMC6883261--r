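#' Moisture-correct a gross-heat measurement
#'
#' Bomb-calorimetry gross heat of a moist sample understates the energy
#' density of the dry matter; the oven-dry value is
#' `GH_OD = GH_sample / (1 - moisture_pct/100)`.
#'
#' @param gross_heat Measured gross heat, MJ kg^-1, `> 0`. Vectorized.
#' @param moisture_pct Sample moisture content, percent, in `[0, 100)`.
#' @return Oven-dry gross heat, MJ kg^-1.
#' @export
#' @examples
#' moisture_corrected_gross_heat(10, 20)  # 12.5
moisture_corrected_gross_heat <- function(gross_heat, moisture_pct) {
  stopifnot(is.numeric(gross_heat), is.numeric(moisture_pct))
  if (any(gross_heat <= 0, na.rm = TRUE)) stop("`gross_heat` must be > 0")
  if (any(moisture_pct < 0 | moisture_pct >= 100, na.rm = TRUE))
    stop("`moisture_pct` must lie in [0, 100)")
  gross_heat / (1 - moisture_pct / 100)
}

#' Summarize energy density across samples
#'
#' Mean, standard deviation and standard error of moisture-corrected gross
#' heat values. Both SD and SE are reported because published dispersion
#' figures do not always say which they are.
#'
#' @param values Corrected gross-heat values, MJ kg^-1; at least 2.
#' @return List with `mean`, `sd`, `se` and `n`.
#' @export
#' @examples
#' summarize_energy_density(c(10, 20))  # mean 15, se 5
summarize_energy_density <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2)
    stop("need at least 2 samples for a standard error")
  s <- stats::sd(values)
  list(mean = mean(values), sd = s, se = s / sqrt(length(values)),
       n = length(values))
}

#' Area-based combustible energy yield
#'
#' Converts a dry-biomass yield to combustible energy per hectare:
#' `biomass (Mg ha^-1) * 1000 (kg Mg^-1) * energy_density (MJ kg^-1)`.
#'
#' @param biomass Dry biomass yield, Mg ha^-1, `>= 0`. Vectorized.
#' @param energy_density Energy density, MJ kg^-1, `>= 0`; defaults to the
#'   measured A. americana mean of 15.44.
#' @return Combustible energy yield, MJ ha^-1.
#' @export
#' @examples
#' area_energy_yield(1)  # 15440
area_energy_yield <- function(biomass,
                              energy_density =
                                epi_constants()$mean_energy_density) {
  stopifnot(is.numeric(biomass), is.numeric(energy_density))
  if (any(biomass < 0, na.rm = TRUE) || any(energy_density < 0, na.rm = TRUE))
    stop("`biomass` and `energy_density` must be >= 0")
  biomass * 1000 * energy_density
}
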