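test_that("weather simulation is seeded, bounded and seasonal", {
  cfg <- weather_sim_config()
  w1 <- simulate_daily_weather(cfg, "2012-04-01", "2012-06-30", seed = 7)
  w2 <- simulate_daily_weather(cfg, "2012-04-01", "2012-06-30", seed = 7)
  expect_identical(w1, w2)                       # bit-identical reruns
  w3 <- simulate_daily_weather(cfg, "2012-04-01", "2012-06-30", seed = 8)
  expect_false(identical(w1, w3))
  expect_equal(nrow(w1), 91)
  expect_true(all(w1$solar_rad_ly >= 0))
  expect_true(all(w1$precip_mm >= 0))
  expect_true(all(w1$t_max_c > w1$t_min_c))
  expect_error(simulate_daily_weather(cfg, "2012-04-02", "2012-04-01"),
               "empty")
  # zero amplitudes and noise give a constant series at the means
  flat <- weather_sim_config(radiation_amplitude = 0, radiation_noise_sd = 0,
                             night_temp_amplitude = 0, temp_noise_sd = 0,
                             precip_monthly_means = rep(0, 12))
  wf <- simulate_daily_weather(flat, "2013-01-01", "2013-03-31", seed = 1)
  expect_true(all(wf$solar_rad_ly == 500))
  expect_true(all(wf$t_min_c == 14))
  expect_true(all(wf$precip_mm == 0))
})

test_that("long-run monthly means track the configured seasonal curve", {
  cfg <- weather_sim_config()
  w <- simulate_daily_weather(cfg, "2006-01-01", "2015-12-31", seed = 21)
  mo <- as.integer(format(w$date, "%m"))
  doy <- as.integer(format(w$date, "%j"))
  expected <- cfg$radiation_mean +
    cfg$radiation_amplitude * cos(2 * pi * (doy - 172) / 365.25)
  for (m in c(1, 6, 9)) {
    sel <- mo == m
    expect_equal(mean(w$solar_rad_ly[sel]), mean(expected[sel]),
                 tolerance = 0.05, label = paste("radiation month", m))
  }
  # precipitation expectation matches the configured monthly means
  yrs <- 10
  totals <- tapply(w$precip_mm, mo, sum) / yrs
  expect_equal(sum(totals), sum(cfg$precip_monthly_means), tolerance = 0.15)
})

test_that("irrigation schedules are nested, summer-centred and conservative", {
  s300 <- irrigation_schedule(300)
  s460 <- irrigation_schedule(460)
  s530 <- irrigation_schedule(530)
  expect_equal(sum(s300), 300)
  expect_equal(sum(s460), 460)
  expect_equal(sum(s530), 530)
  expect_setequal(which(s300 > 0), 6:9)
  expect_setequal(which(s460 > 0), 5:10)
  expect_setequal(which(s530 > 0), 4:10)
  expect_true(all(which(s300 > 0) %in% which(s460 > 0)))
  expect_true(all(which(s460 > 0) %in% which(s530 > 0)))
  expect_equal(irrigation_schedule(0), numeric(12))
})

test_that("monthly aggregation matches hand-computed summaries", {
  flat <- weather_sim_config(radiation_amplitude = 0, radiation_noise_sd = 0,
                             night_temp_amplitude = 0, temp_noise_sd = 0,
                             precip_monthly_means = rep(0, 12))
  w <- simulate_daily_weather(flat, "2013-04-01", "2013-05-31", seed = 1)
  irr <- irrigation_schedule(530)
  m <- aggregate_monthly(w, irr, latitude = 33)
  expect_equal(nrow(m), 2)
  expect_equal(m$total_moisture_mm, irr[4:5])  # conservation: precip 0
  expect_equal(m$t_min_night_c, c(14, 14))
  dl <- monthly_mean_daylight_hours(33, 4, 2013)
  expect_equal(m$mean_daily_par[1], mean_par_from_daily_radiation(500, dl))
  # independent re-aggregation oracle on a noisy series
  wn <- simulate_daily_weather(weather_sim_config(), "2014-02-01",
                               "2014-03-31", seed = 5)
  mn <- aggregate_monthly(wn, numeric(12), latitude = 33)
  feb <- format(wn$date, "%m") == "02"
  expect_equal(mn$total_moisture_mm[1], sum(wn$precip_mm[feb]))
  expect_equal(mn$t_max_day_c[1], mean(wn$t_max_c[feb]))
  # user-supplied monthly day lengths override the astronomical values
  mo <- aggregate_monthly(wn, numeric(12), daylight_hours = rep(12, 12))
  expect_equal(mo$mean_daily_par[1],
               mean_par_from_daily_radiation(mean(wn$solar_rad_ly[feb]), 12))
  # partial months are refused
  expect_error(aggregate_monthly(wn[-1, ], numeric(12)), "incomplete")
})

test_that("CAM traces integrate to the light-response target", {
  for (ppfd in c(250, 500, 750, 1000, 1250)) {
    sim <- simulate_cam_trace(cam_trace_config(ppfd, noise_sd = 0))
    expect_equal(sim$true_integral, oracle_assim_quadratic(ppfd))
    expect_equal(integrate_daily_net(sim$trace), sim$true_integral,
                 tolerance = 2e-3, label = paste("ppfd", ppfd))
  }
  s1250 <- simulate_cam_trace(cam_trace_config(1250, noise_sd = 0))
  expect_equal(integrate_daily_net(s1250$trace), 0.6244, tolerance = 1e-3)
  # dusk spike suppressed at 100 umol: light-period flux never positive
  s100 <- simulate_cam_trace(cam_trace_config(100, noise_sd = 0))
  day <- s100$trace$light_on
  expect_true(all(s100$trace$assimilation[day] <= 1e-12))
  # at 250 and above phase 4 shows positive light-period assimilation
  s250 <- simulate_cam_trace(cam_trace_config(250, noise_sd = 0))
  expect_gt(max(s250$trace$assimilation[s250$trace$light_on]), 0)
  # seeded determinism of the noisy generator
  a <- simulate_cam_trace(cam_trace_config(750), seed = 3)
  b <- simulate_cam_trace(cam_trace_config(750), seed = 3)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_cam_trace(cam_trace_config(750), seed = 4)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_cam_trace(cam_trace_config(500), seed = 9))
  invisible(simulate_daily_weather(weather_sim_config(), "2012-01-01",
                                   "2012-01-31", seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("yield datasets follow the generating line", {
  truth <- yield_model(1.7607, -14.774, "biomass")
  d0 <- simulate_yield_dataset(truth, c(14.47, 17.17, 20.58), noise_sd = 0)
  expect_equal(d0$yield, pmax(0, 1.7607 * d0$epi_sum - 14.774))
  d1 <- simulate_yield_dataset(truth, 1:20, noise_sd = 2, seed = 6)
  expect_identical(d1, simulate_yield_dataset(truth, 1:20, noise_sd = 2,
                                              seed = 6))
  expect_true(all(d1$yield >= 0))
})

test_that("cumulative EPI is monotone in the irrigation total", {
  cfg <- weather_sim_config()
  w <- simulate_daily_weather(cfg, "2012-04-01", "2015-06-30", seed = 17)
  sums <- vapply(c(300, 460, 530, 780), function(tot) {
    idx <- monthly_indices(aggregate_monthly(w, irrigation_schedule(tot)))
    idx$epi <- monthly_epi(idx)
    cumulative_epi(idx)
  }, numeric(1))
  expect_true(all(diff(sums) >= 0))
  expect_true(all(diff(sums[1:3]) > 0))  # mirrors 14.47 < 17.17 < 20.58
})
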