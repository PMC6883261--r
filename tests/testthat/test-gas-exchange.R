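test_that("flux_trace validates its invariants", {
  expect_error(flux_trace(c(0, 300), c(1, 1)), "at least 3")
  expect_error(flux_trace(c(0, 300, 300), c(1, 1, 1)),
               "strictly increasing")
  expect_error(flux_trace(c(0, 300, 200000), c(1, 1, 1)), "span")
  tr <- flux_trace(c(0, 300, 600), c(1, -0.5, 1))
  expect_s3_class(tr, "flux_trace")
})

test_that("Simpson integration is exact for polynomials up to cubic", {
  # constant integrand over 24 h
  expect_equal(integrate_daily_net(make_uniform_trace(function(t) rep(1, length(t)))),
               0.0864)
  # cubic in time: analytic integral of a + b t + c t^2 + d t^3
  co <- c(2, 3e-5, -1.5e-9, 1e-14)
  f <- function(t) co[1] + co[2] * t + co[3] * t^2 + co[4] * t^3
  analytic <- sum(co / 1:4 * 86400^(1:4)) * 1e-6
  expect_equal(integrate_daily_net(make_uniform_trace(f)), analytic,
               tolerance = 1e-12)
  # net efflux trace integrates negative
  expect_lt(integrate_daily_net(make_uniform_trace(function(t) rep(-0.1, length(t)))),
            0)
})

test_that("Simpson agrees with the trapezoid oracle on smooth 5-min traces", {
  f <- function(t) 2 + sin(2 * pi * t / 86400) + 0.5 * cos(4 * pi * t / 86400)
  tr <- make_uniform_trace(f)
  simpson <- integrate_daily_net(tr)
  trap <- oracle_trapezoid(tr$times, tr$assimilation)
  expect_equal(simpson, trap, tolerance = 1e-6)
})

test_that("non-uniform grids and odd interval counts are handled", {
  # drop samples from a uniform grid: quadratic still integrated exactly
  t <- seq(0, 86400, by = 300)
  set.seed(7)
  keep <- sort(c(1, sample(2:(length(t) - 1), 200), length(t)))
  f <- function(t) 1 + 1e-5 * t - 2e-10 * t^2
  tq <- t[keep]
  # ensure an even interval count so pure Simpson applies
  if ((length(tq) - 1) %% 2 == 1) tq <- tq[-2]
  analytic <- (86400 + 1e-5 / 2 * 86400^2 - 2e-10 / 3 * 86400^3) * 1e-6
  expect_equal(integrate_daily_net(flux_trace(tq, f(tq))), analytic,
               tolerance = 1e-9)
  # odd interval count falls back to a trailing trapezoid, close but defined
  t_odd <- seq(0, 86400, by = 300)[-2]
  expect_equal(integrate_daily_net(flux_trace(t_odd, f(t_odd))), analytic,
               tolerance = 1e-4)
})

test_that("light-response fitting interpolates noiseless quadratics", {
  x <- c(100, 250, 500, 750, 1000, 1250)
  fit <- fit_light_response(x, oracle_assim_quadratic(x))
  expect_equal(fit$a, -4e-7, tolerance = 1e-9)
  expect_equal(fit$b, 0.001, tolerance = 1e-9)
  expect_equal(fit$c, -0.0006, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_error(fit_light_response(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(fit_light_response(c(100, 200), c(1, 2)), "distinct")
  expect_warning(fit_light_response(c(1, 2, 3, 4), c(1, 4, 9, 16)),
                 "not saturating")
})

test_that("noisy refits recover the generating coefficients", {
  x <- rep(c(100, 250, 500, 750, 1000, 1250), each = 6)
  set.seed(99)
  y <- oracle_assim_quadratic(x) + rnorm(length(x), 0, 0.01)
  fit <- fit_light_response(x, y)
  expect_equal(fit$a, -4e-7, tolerance = 0.15)
  expect_equal(fit$b, 0.001, tolerance = 0.15)
  pk <- response_peak(fit)
  expect_equal(unname(pk["ppfd"]), 1250, tolerance = 0.05)
  expect_gt(fit$r2, 0.9)
})

test_that("response peak is the closed-form vertex", {
  pk <- response_peak(light_response_fit(-4e-7, 0.001, -0.0006))
  expect_equal(unname(pk["ppfd"]), 1250)
  expect_equal(unname(pk["uptake"]), 0.6244)
  expect_equal(unname(response_peak(light_response_fit(-1, 2, 0))),
               c(1, 1))
  expect_error(response_peak(light_response_fit(1e-7, 0.001, 0)),
               "maximum")
})

test_that("index-curve normalization sets the vertex to exactly 1", {
  fit <- light_response_fit(-4e-7, 0.001, -0.0006)
  curve <- derive_light_index_curve(fit)
  expect_equal(unname(response_peak(curve)["uptake"]), 1, tolerance = 1e-12)
  expect_equal(curve$a, -4e-7 / 0.6244)
  expect_equal(curve$c, -0.0006 / 0.6244)  # value at 0 is ~-0.000961
  # idempotent: normalizing twice changes nothing
  twice <- derive_light_index_curve(curve)
  expect_equal(twice[c("a", "b", "c")], curve[c("a", "b", "c")])
  expect_error(derive_light_index_curve(light_response_fit(-1, 0, -1)),
               "positive")
})

test_that("CAM phases follow the light-on transitions", {
  t <- seq(0, 86400, by = 600)
  light <- t >= 6 * 3600 & t < 18 * 3600
  tr <- flux_trace(t, rep(1, length(t)), light)
  ph <- cam_phases(tr)
  expect_setequal(unique(ph), 1:4)
  expect_true(all(ph[!light] == 1))
  expect_true(all(ph[t >= 6 * 3600 & t < 7 * 3600] == 2))
  expect_true(all(ph[light & t > 16 * 3600] == 4))
})
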