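# Independent oracles, deliberately written along different paths than the
# implementation they check.

# Day length by bisection on the solar elevation angle (implementation uses
# the closed-form sunset hour angle instead).
oracle_daylight_hours <- function(latitude, day_of_year) {
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- latitude * pi / 180
  elev <- function(hour_angle_deg) {
    h <- hour_angle_deg * pi / 180
    asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(h))
  }
  if (elev(180) >= 0) return(24)   # polar day
  if (elev(0) <= 0) return(0)      # polar night
  lo <- 0; hi <- 180
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (elev(mid) > 0) lo <- mid else hi <- mid
  }
  2 * lo / 15
}

# plain trapezoid integrator (umol.s -> mol)
oracle_trapezoid <- function(times, assim) {
  sum(diff(times) * (head(assim, -1) + tail(assim, -1)) / 2) * 1e-6
}

# naive re-summation oracle for mean / standard error
oracle_mean_se <- function(x) {
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / (length(x) - 1)
  list(mean = m, se = sqrt(v / length(x)))
}

# the fitted assimilation quadratic, written out directly
oracle_assim_quadratic <- function(x) -4e-7 * x^2 + 0.001 * x - 0.0006

# the acidity quintic in percent, written out directly
oracle_acidity <- function(x) {
  -2e-5 * x^5 + 0.0013 * x^4 - 0.0169 * x^3 - 0.3875 * x^2 +
    10.527 * x + 35.194
}

make_uniform_trace <- function(f, interval = 300, span = 86400) {
  t <- seq(0, span, by = interval)
  flux_trace(t, f(t))
}
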