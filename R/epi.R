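#' Monthly environmental productivity index
#'
#' The EPI for a month is the product of its light, water and temperature
#' indices; since each lies in `[0, 1]` so does the product, and any single
#' fully limiting factor zeroes the month.
#'
#' @param indices Data frame with columns `light`, `water`, `temperature`
#'   (as returned by [monthly_indices()]), or a numeric matrix/data frame of
#'   the three columns.
#' @return Numeric vector of monthly EPI values in `[0, 1]`.
#' @export
#' @examples
#' monthly_epi(data.frame(light = 0.8, water = 0.5, temperature = 0.9))
monthly_epi <- function(indices) {
  need <- c("light", "water", "temperature")
  if (!all(need %in% names(indices)))
    stop("`indices` must have columns light, water, temperature")
  indices$light * indices$water * indices$temperature
}

#' Cumulative EPI over a crop lifetime
#'
#' Sums monthly EPI values over a caller-specified window of contiguous
#' months (crop lifetimes span multiple calendar years; the window used for
#' yield comparison is a modelling choice).
#'
#' @param epi_series Data frame with columns `year`, `month` and `epi`, in
#'   chronological order.
#' @param from,to Optional `"YYYY-MM"` strings delimiting the window
#'   (inclusive); default is the whole series.
#' @return The summed EPI over the window.
#' @export
cumulative_epi <- function(epi_series, from = NULL, to = NULL) {
  need <- c("year", "month", "epi")
  if (!all(need %in% names(epi_series)))
    stop("`epi_series` must have columns year, month, epi")
  key <- epi_series$year * 12 + (epi_series$month - 1)
  if (any(diff(key) != 1))
    stop("`epi_series` months must be contiguous and ordered")
  lo <- if (is.null(from)) min(key) else parse_ym(from)
  hi <- if (is.null(to)) max(key) else parse_ym(to)
  keep <- key >= lo & key <= hi
  if (!any(keep)) stop("empty month window")
  sum(epi_series$epi[keep])
}

parse_ym <- function(x) {
  m <- regmatches(x, regexec("^(\\d{4})-(\\d{2})$", x))[[1]]
  if (length(m) != 3) stop("month tags must be 'YYYY-MM', got: ", x)
  as.integer(m[2]) * 12 + (as.integer(m[3]) - 1)
}

#' Construct a linear yield model
#'
#' Yield (dry biomass or combustible energy) is modelled as a linear
#' function of cumulative EPI: `yield = slope * epi_sum + intercept`.
#'
#' @param slope,intercept Model coefficients; yield units per EPI sum and
#'   yield units respectively.
#' @param kind `"biomass"` (Mg ha^-1) or `"energy"` (MJ ha^-1).
#' @param fit_r2 Optional coefficient of determination.
#' @return A `yield_model` object.
#' @seealso [agave_yield_models()] for the fitted A. americana coefficients.
#' @export
yield_model <- function(slope, intercept, kind = c("biomass", "energy"),
                        fit_r2 = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept, kind = kind,
                 fit_r2 = fit_r2),
            class = "yield_model")
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf("Linear %s model: yield = %s * EPI_sum + %s\n",
              x$kind, format(x$slope), format(x$intercept)))
  if (!is.na(x$fit_r2)) cat("R^2 =", format(x$fit_r2, digits = 4), "\n")
  invisible(x)
}

#' Fitted yield models for A. americana
#'
#' The linear regressions of field yield on cumulative EPI:
#' \describe{
#'   \item{biomass_printed}{`y = 0.7607 x - 14.774`, as published. At the
#'     highest-irrigation EPI sum (20.58) this predicts only ~0.88 Mg ha^-1.}
#'   \item{biomass_corrected}{`y = 1.7607 x - 14.774`. The energy regression
#'     divided by the mean energy density (27 290 / 15 440 = 1.77 and
#'     228 335 / 15 440 = 14.79) implies the published biomass slope dropped
#'     a leading digit; this variant restores internal consistency. The
#'     published slope remains the default elsewhere for fidelity.}
#'   \item{energy}{`y = 27 290 x - 228 335` MJ ha^-1.}
#' }
#'
#' @return Named list of three [yield_model()] objects.
#' @export
agave_yield_models <- function() {
  k <- epi_constants()
  list(
    biomass_printed = yield_model(k$biomass_slope_printed,
                                  k$biomass_intercept, "biomass"),
    biomass_corrected = yield_model(k$biomass_slope_corrected,
                                    k$biomass_intercept, "biomass"),
    energy = yield_model(k$energy_slope, k$energy_intercept, "energy")
  )
}

predict_yield <- function(epi_sum, model, kind) {
  stopifnot(inherits(model, "yield_model"), is.numeric(epi_sum))
  if (any(epi_sum < 0, na.rm = TRUE)) stop("`epi_sum` must be >= 0")
  if (model$kind != kind)
    stop("model kind is '", model$kind, "', expected '", kind, "'")
  pmax(0, model$slope * epi_sum + model$intercept)
}

#' Predict dry biomass from cumulative EPI
#'
#' Evaluates a linear biomass [yield_model()] at a cumulative EPI value,
#' floored at 0 (negative biomass being unphysical).
#'
#' @param epi_sum Cumulative EPI, `>= 0`. Vectorized.
#' @param model A `yield_model` of kind `"biomass"`; defaults to the
#'   published line.
#' @return Predicted dry biomass, Mg ha^-1.
#' @export
#' @examples
#' predict_biomass(20.58)  # 0.8812 with the published slope
#' predict_biomass(20.58, agave_yield_models()$biomass_corrected)
predict_biomass <- function(epi_sum,
                            model = agave_yield_models()$biomass_printed) {
  predict_yield(epi_sum, model, "biomass")
}

#' Predict combustible energy yield from cumulative EPI
#'
#' @param epi_sum Cumulative EPI, `>= 0`. Vectorized.
#' @param model A `yield_model` of kind `"energy"`; defaults to the
#'   published line.
#' @return Predicted combustible energy yield, MJ ha^-1, floored at 0.
#' @export
#' @examples
#' predict_energy(20.58)  # 333293.2
predict_energy <- function(epi_sum,
                           model = agave_yield_models()$energy) {
  predict_yield(epi_sum, model, "energy")
}

#' Fit a linear yield model from observations
#'
#' Ordinary least squares of observed yield on cumulative EPI.
#'
#' @param epi_sum Cumulative EPI per plot/treatment; at least 2 distinct
#'   values.
#' @param yield Observed yield in the model's units.
#' @param kind `"biomass"` or `"energy"`.
#' @return A [yield_model()] with `fit_r2` filled in.
#' @export
fit_linear_yield <- function(epi_sum, yield, kind = c("biomass", "energy")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(epi_sum), is.numeric(yield),
            length(epi_sum) == length(yield))
  if (length(unique(epi_sum)) < 2)
    stop("need at least 2 distinct EPI sums to fit a line")
  fit <- stats::lm(yield ~ epi_sum)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((yield - mean(yield))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  yield_model(unname(stats::coef(fit)[2]), unname(stats::coef(fit)[1]),
              kind, fit_r2 = r2)
}
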