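#' Physical and model constants
#'
#' Returns the single record of conversion factors and fitted-model
#' coefficients used throughout the package. Keeping them in one place makes
#' the choice between the published ("printed") factors and their physically
#' exact counterparts explicit and auditable.
#'
#' Notable entries:
#' \describe{
#'   \item{langley_to_wh}{11.622 Wh m^-2 per Langley, the published factor.
#'     The physically exact value 41868/3600 = 11.63 differs by <0.1%; the
#'     published factor is the default so converted series match the
#'     published pipeline. See \code{langley_to_wh_physical}.}
#'   \item{luminous_efficacy}{110 lumens W^-1, global annual average used to
#'     convert mean irradiance to illuminance.}
#'   \item{klux_to_ppfd}{18 umol photons m^-2 s^-1 per klux of daylight.}
#'   \item{assim_quadratic}{Coefficients (intercept, linear, quadratic) of
#'     the fitted 24 h net CO2 uptake response to PPFD, mol d^-1.}
#'   \item{light_index_quadratic}{The published (rounded) light-index
#'     quadratic; its maximum is ~0.905, see \code{\link{light_index}}.}
#'   \item{acidity_quintic}{Titratable-acidity response to night temperature,
#'     percent of maximum, coefficients in ascending degree order.}
#'   \item{temp_index_quintic}{The published temperature-index quintic
#'     (ascending order); retained for auditability, see
#'     \code{\link{temperature_index}}.}
#'   \item{benzoic_acid_cal_g}{6318 cal g^-1, calorimeter calibration
#'     standard; \code{cal_to_j} = 4.184 J cal^-1 (thermochemical calorie)
#'     makes this 26.43 MJ kg^-1.}
#' }
#'
#' @return A named list of constants.
#' @export
#' @examples
#' epi_constants()$langley_to_wh
epi_constants <- function() {
  list(
    # radiation chain
    langley_to_joule      = 41868,            # J m^-2 per Langley
    langley_to_wh         = 11.622,           # published factor, Wh m^-2
    langley_to_wh_physical = 41868 / 3600,    # = 11.63
    luminous_efficacy     = 110,              # lm W^-1
    klux_to_ppfd          = 18,               # umol m^-2 s^-1 per klux
    # net effect: PPFD per (Langley / daylight hour)
    langley_per_hour_to_ppfd = 11.622 * 110 * 18 / 1000,  # 23.01156

    # 24 h light response, mol CO2 m^-2 d^-1 vs PPFD (ascending order)
    assim_quadratic       = c(-0.0006, 0.001, -4e-7),
    # published light-index quadratic (ascending order)
    light_index_quadratic = c(-0.001, 0.0016, -7e-7),

    # night-temperature responses (ascending order, degree 0..5)
    acidity_quintic    = c(35.194, 10.527, -0.3875, -0.0169, 0.0013, -2e-5),
    temp_index_quintic = c(0.3520, 0.1052, -3.878e-3, -1.66e-4, 0.13e-4,
                           -0.2e-7),
    temp_cease_low     = -3,    # degC, productivity ceases at or below
    temp_cease_high    = 38,    # degC, productivity ceases at or above
    leaf_temp_offset   = 2,     # degC above air minimum
    daytime_temp_warn  = 45,    # degC, assimilation unaffected below this

    # water index line (monthly moisture, mm)
    water_index_slope     = 0.0279,
    water_index_intercept = -0.2851,

    # yield regressions vs cumulative EPI
    biomass_slope_printed   = 0.7607,
    biomass_slope_corrected = 1.7607,
    biomass_intercept       = -14.774,
    energy_slope            = 27290,
    energy_intercept        = -228335,

    # calorimetry
    benzoic_acid_cal_g = 6318,
    cal_to_j           = 4.184,
    mean_energy_density = 15.44   # MJ kg^-1 oven-dry biomass
  )
}

# evaluate a polynomial given ascending-order coefficients; vectorized in x
polyval_asc <- function(coefs, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coefs))) y <- y * x + coefs[k]
  y
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
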