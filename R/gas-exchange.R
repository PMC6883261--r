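#' Construct a 24 h gas-exchange flux trace
#'
#' A `flux_trace` holds one diel cuvette record: elapsed time, net CO2
#' assimilation (which may be negative -- CAM leaves commonly show small
#' effluxes in phases 2 and 3), and whether the lights were on at each
#' sample. Typical records are logged at 5 min intervals over ~24 h.
#'
#' @param times Seconds from trace start; strictly increasing, `>= 3` values.
#' @param assimilation Net CO2 assimilation, umol m^-2 s^-1. Negative values
#'   are retained, never floored.
#' @param light_on Logical vector: lights on at each sample.
#' @return An object of class `flux_trace` (a validated data frame).
#' @export
flux_trace <- function(times, assimilation,
                       light_on = rep(FALSE, length(times))) {
  stopifnot(is.numeric(times), is.numeric(assimilation))
  n <- length(times)
  if (n < 3) stop("a flux trace needs at least 3 samples")
  if (length(assimilation) != n || length(light_on) != n)
    stop("`times`, `assimilation` and `light_on` must have equal length")
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (diff(range(times)) > 86400 + min(diff(times)))
    stop("trace span exceeds 24 h by more than one sampling interval")
  structure(data.frame(times = times, assimilation = assimilation,
                       light_on = as.logical(light_on)),
            class = c("flux_trace", "data.frame"))
}

# Composite Simpson's rule on a possibly non-uniform grid. Successive point
# triples are fitted exactly by a parabola; an odd trailing interval falls
# back to the trapezoid rule. Exact for polynomials up to cubic on uniform
# grids with an even interval count.
simpson_integral <- function(x, y) {
  n <- length(x)
  n_int <- n - 1
  total <- 0
  i <- 1
  while (i + 1 <= n - (n_int %% 2)) {
    h0 <- x[i + 1] - x[i]
    h1 <- x[i + 2] - x[i + 1]
    total <- total + (h0 + h1) / 6 *
      ((2 - h1 / h0) * y[i] +
         (h0 + h1)^2 / (h0 * h1) * y[i + 1] +
         (2 - h0 / h1) * y[i + 2])
    i <- i + 2
  }
  if (n_int %% 2 == 1)
    total <- total + (x[n] - x[n - 1]) * (y[n] + y[n - 1]) / 2
  total
}

#' Integrate a diel trace to net daily CO2 uptake
#'
#' Integrates a [flux_trace()] over its full span with the composite
#' Simpson's rule and converts from umol.s to mol (x 1e-6). Non-uniform
#' sample spacing is supported (loggers drop samples); when the number of
#' intervals is odd the final interval is handled by the trapezoid rule.
#' The result may be negative: low-light CAM traces can show net 24 h
#' carbon loss.
#'
#' @param trace A [flux_trace()], or a data frame with columns `times` and
#'   `assimilation`.
#' @return Net CO2 uptake in mol m^-2 per trace span (~24 h).
#' @export
#' @examples
#' tr <- flux_trace(seq(0, 86400, by = 300),
#'                  rep(1, 289))
#' integrate_daily_net(tr)  # 0.0864 mol
integrate_daily_net <- function(trace) {
  if (!inherits(trace, "flux_trace"))
    trace <- flux_trace(trace$times, trace$assimilation,
                        if (!is.null(trace$light_on)) trace$light_on
                        else rep(FALSE, length(trace$times)))
  simpson_integral(trace$times, trace$assimilation) * 1e-6
}

#' Fit the quadratic light response of 24 h CO2 uptake
#'
#' Ordinary least-squares fit of `uptake = a*ppfd^2 + b*ppfd + c` to
#' (PPFD, net daily uptake) pairs, the saturating response of integrated
#' CAM carbon gain to growth irradiance. A negative `a` gives an interior
#' maximum (the light saturation point); a warning is issued otherwise.
#'
#' @param ppfd PPFD levels, umol m^-2 s^-1; at least 3 distinct values.
#' @param uptake Net 24 h CO2 uptake at each level, mol d^-1.
#' @return A `light_response_fit`: list with coefficients `a`, `b`, `c`,
#'   `r2`, and the number of points `n`.
#' @seealso [response_peak()], [derive_light_index_curve()]
#' @export
fit_light_response <- function(ppfd, uptake) {
  stopifnot(is.numeric(ppfd), is.numeric(uptake),
            length(ppfd) == length(uptake))
  if (length(unique(ppfd)) < 3)
    stop("need at least 3 distinct PPFD values for a quadratic fit")
  fit <- stats::lm(uptake ~ ppfd + I(ppfd^2))
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((uptake - mean(uptake))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out <- light_response_fit(a = unname(cf[3]), b = unname(cf[2]),
                            c = unname(cf[1]), r2 = r2,
                            n = length(ppfd))
  if (out$a >= 0)
    warning("fitted quadratic is not saturating (a >= 0); ",
            "no interior light optimum exists")
  out
}

#' Assemble a light-response fit from known coefficients
#'
#' @param a,b,c Quadratic, linear and intercept coefficients of
#'   `uptake = a*x^2 + b*x + c` with `x` in umol m^-2 s^-1 and uptake in
#'   mol d^-1.
#' @param r2 Optional coefficient of determination in `[0, 1]`.
#' @param n Optional number of points behind the fit.
#' @return A `light_response_fit` object.
#' @export
#' @examples
#' # the fitted A. americana response
#' light_response_fit(-4e-7, 0.001, -0.0006)
light_response_fit <- function(a, b, c, r2 = NA_real_, n = NA_integer_) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("`r2` must lie in [0, 1]")
  structure(list(a = a, b = b, c = c, r2 = r2, n = n),
            class = "light_response_fit")
}

#' @export
print.light_response_fit <- function(x, ...) {
  cat("Quadratic light response: uptake = ",
      format(x$a), "*x^2 + ", format(x$b), "*x + ", format(x$c), "\n",
      sep = "")
  if (!is.na(x$r2)) cat("R^2 =", format(x$r2, digits = 4), "\n")
  if (x$a < 0) {
    pk <- response_peak(x)
    cat("Saturation: ", format(pk[["ppfd"]]), " umol m^-2 s^-1, ",
        format(pk[["uptake"]]), " mol d^-1\n", sep = "")
  }
  invisible(x)
}

#' Light saturation point of a fitted response
#'
#' Vertex of the quadratic: PPFD at maximum `-b/(2a)` and maximum uptake
#' `c - b^2/(4a)`. For the fitted A. americana response this is
#' (1250 umol m^-2 s^-1, 0.6244 mol d^-1).
#'
#' @param fit A `light_response_fit` with `a < 0`.
#' @return Named numeric vector `c(ppfd = , uptake = )`.
#' @export
#' @examples
#' response_peak(light_response_fit(-4e-7, 0.001, -0.0006))
response_peak <- function(fit) {
  stopifnot(inherits(fit, "light_response_fit"))
  if (fit$a >= 0) stop("no interior maximum: quadratic coefficient a >= 0")
  c(ppfd = -fit$b / (2 * fit$a),
    uptake = fit$c - fit$b^2 / (4 * fit$a))
}

#' Normalize a light response into a 0--1 index curve
#'
#' Divides the quadratic's coefficients by its vertex value so the curve's
#' maximum is exactly 1, giving a light index: the proportion of maximum
#' 24 h carbon gain attainable at a given PPFD.
#'
#' @param fit A `light_response_fit` with `a < 0` and a positive maximum.
#' @return A `light_response_fit` whose vertex value is exactly 1.
#' @export
derive_light_index_curve <- function(fit) {
  stopifnot(inherits(fit, "light_response_fit"))
  pk <- response_peak(fit)
  v <- pk[["uptake"]]
  if (v <= 0)
    stop("vertex value must be positive to normalize into an index")
  light_response_fit(fit$a / v, fit$b / v, fit$c / v, r2 = fit$r2, n = fit$n)
}

#' Label the CAM phases of a diel trace
#'
#' Annotates each sample with the classical CAM phase keyed to the
#' `light_on` flag: phase 1 (dark, nocturnal fixation), phase 2 (first
#' 1 h of light, dawn), phase 3 (mid-light, stomata closed), phase 4
#' (final 2 h of light, dusk reopening). Purely a labelling aid; the
#' integrator ignores phases.
#'
#' @param trace A [flux_trace()].
#' @param dawn_window Seconds after lights-on labelled phase 2 (default 3600).
#' @param dusk_window Seconds before lights-off labelled phase 4
#'   (default 7200).
#' @return Integer vector of phases (1--4), one per sample.
#' @export
cam_phases <- function(trace, dawn_window = 3600, dusk_window = 7200) {
  stopifnot(inherits(trace, "flux_trace"))
  phase <- ifelse(trace$light_on, 3L, 1L)
  on <- which(trace$light_on)
  if (length(on)) {
    t_on <- trace$times[min(on)]
    t_off <- trace$times[max(on)]
    light <- trace$light_on
    phase[light & trace$times < t_on + dawn_window] <- 2L
    phase[light & trace$times > t_off - dusk_window] <- 4L
  }
  phase
}
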