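# Synthetic barn-data generator: environment, pig counts, consumption
# surface, batch assembly, fault injection.

test_that("degenerate environment config collapses to the annual sinusoid", {
  cfg <- environment_config(diurnal_amplitude = 0, noise_sd = 0, nh3_sd = 0,
                            humidity_sd = 0, co2_sd = 0)
  env <- simulate_environment(48, cfg = cfg, seed = 3)
  # within a day all hours share the annual-sinusoid value, up to the small
  # annual drift accumulated across 24 h (slope ~ 0.03 degC/day in January)
  day1 <- env$temperature[1:24]
  expect_lt(diff(range(day1)), 0.05)
  expect_equal(env$temperature_noise, rep(0, 48))
  # identical seeds give bit-identical tables
  expect_identical(simulate_environment(200, seed = 7),
                   simulate_environment(200, seed = 7))
})

test_that("temperature noise has the configured lag-1 autocorrelation", {
  cfg <- environment_config(noise_ar = 0.8)
  env <- simulate_environment(10000, cfg = cfg, seed = 5)
  x <- env$temperature_noise
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.8), 0.05)
})

test_that("environment config rejects invalid values", {
  expect_error(environment_config(noise_ar = 1), "autocorrelation")
  expect_error(environment_config(annual_amplitude = -1), "amplitude")
  expect_error(environment_config(noise_sd = NaN), "non-finite")
})

test_that("pig counts are non-increasing and calibrated to total mortality", {
  expect_equal(simulate_pig_counts(700, 0, 100, seed = 1), rep(700L, 100))
  for (s in 1:20)
    expect_true(all(diff(simulate_pig_counts(690, 0.0339, 500, seed = s)) <= 0))
  finals <- vapply(1:200, function(s)
    tail(simulate_pig_counts(690, 0.0339, 2520, seed = s), 1), numeric(1))
  expect_lt(abs(mean(finals) - 690 * (1 - 0.0339)), 2)
})

test_that("model-truth surface is the linear predictor of the shipped model", {
  m <- barn_truth_model()
  # no harmonics / covariates: constant mu
  pz <- armax_params(mu = 3, eta = c(S1 = 0, S2 = 0, S3 = 0, S4 = 0,
                                     C1 = 0, C2 = 0, C3 = 0, C4 = 0,
                                     T = 0, NH3 = 0, N = 0))
  out <- mean_consumption_profile(0:23, 1, covariates = list(T = 10, NH3 = 12),
                                  mode = "model-truth", params = pz)
  expect_equal(out, rep(3, 24))
  # harmonic part equals a directly coded Fourier sum
  h <- 0:23
  eta <- m$params$eta
  direct <- rowSums(sapply(1:4, function(k)
    eta[[paste0("S", k)]] * sin(2 * pi * k * h / 24) +
      eta[[paste0("C", k)]] * cos(2 * pi * k * h / 24)))
  got <- mean_consumption_profile(h, 1, covariates = list(T = 0, NH3 = 0),
                                  mode = "model-truth", params = m$params) -
    m$params$mu - eta[["N"]] * 1
  expect_equal(unname(got), direct, tolerance = 1e-12)
  expect_error(mean_consumption_profile(0, 1, covariates = list(T = 1),
                                        mode = "model-truth"), "NH3")
})

test_that("farm-realistic surface matches the first-week calibration", {
  hod <- rep(0:23, 7)
  fday <- rep(1:7, each = 24)
  surf <- mean_consumption_profile(hod, fday, mode = "farm-realistic")
  daily <- tapply(surf, fday, sum) / 1000  # L/pig/day
  expect_lt(abs(mean(daily) - 2.35), 0.15)
  expect_true(all(surf >= 0))
})

test_that("noise-free uncorrupted batch reproduces the mean surface exactly", {
  cfg <- batch_config(duration_weeks = 1, corruption = no_corruption(),
                      calibration = farm_calibration(rel_noise_sd = 0),
                      seed = 4)
  b <- simulate_batch(cfg)
  agg <- aggregate_hourly(b$raw)
  got <- 1000 * agg$volume_L / agg$pig_count
  expect_equal(got, b$clean$consumption, tolerance = 1e-9)
  hod <- as.integer(format(b$clean$timestamp, "%H"))
  expect_equal(b$clean$consumption,
               mean_consumption_profile(hod, b$clean$fattening_day,
                                        mode = "farm-realistic"),
               tolerance = 1e-9)
})

test_that("model-truth batch noise follows the requested ARMA structure", {
  spec <- armax_spec(1, 0, ar_lags = 1, regressors = character(),
                     intercept = TRUE)
  pars <- armax_params(mu = 0, phi = c(`1` = 0.5), sigma2 = 1)
  cfg <- batch_config(mode = "model-truth", duration_weeks = 6,
                      corruption = no_corruption(),
                      model = list(spec = spec, params = pars), seed = 9)
  b <- simulate_batch(cfg)
  x <- b$clean$consumption
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.5), 0.05)
})

test_that("non-stationary truth parameters are rejected with the root modulus", {
  spec <- armax_spec(1, 0, ar_lags = 1, regressors = character())
  pars <- armax_params(phi = c(`1` = 1.02), sigma2 = 1)
  cfg <- batch_config(mode = "model-truth", duration_weeks = 1,
                      model = list(spec = spec, params = pars), seed = 1)
  expect_error(simulate_batch(cfg), "root modulus")
})

test_that("corruption is disabled by zero rates and logged when active", {
  rd <- flat_readings(100)
  out0 <- corrupt_readings(rd, no_corruption(), seed = 1)
  expect_identical(out0$readings, rd)
  expect_equal(nrow(out0$ledger), 0)

  out <- corrupt_readings(rd, corruption_rates(extreme = 0.2, negative = 0.1,
                                               consecutive = 0.05, missing = 0.05),
                          seed = 2)
  agg <- aggregate_hourly(out$readings)
  cons <- 1000 * agg$volume_L / agg$pig_count
  # every injected extreme exceeds 10 L/pig/h; every negative drops below zero
  ext_hours <- out$ledger$hour[out$ledger$kind == "extreme"]
  expect_true(all(cons[agg$timestamp %in% ext_hours] > 10000))
  neg_hours <- out$ledger$hour[out$ledger$kind == "negative"]
  expect_true(all(cons[agg$timestamp %in% neg_hours] < 0))
  # missing faults leave the hour short of readings
  mis_hours <- out$ledger$hour[out$ledger$kind == "missing"]
  expect_true(all(agg$missing[agg$timestamp %in% mis_hours]))
})

test_that("injected-fault counts follow the configured binomial rate", {
  rd <- flat_readings(20000)
  out <- corrupt_readings(rd, corruption_rates(extreme = 0.0748, negative = 0,
                                               consecutive = 0, missing = 0,
                                               non_drinking = 0), seed = 11)
  frac <- sum(out$ledger$kind == "extreme") / 20000
  expect_lt(abs(frac - 0.0748), 0.005)
})

test_that("the fault ledger is exactly the raw-vs-clean difference set", {
  b <- simulate_batch(batch_config(duration_weeks = 4, seed = 13))
  agg <- aggregate_hourly(b$raw[b$raw$usage == "drinking", ])
  cons <- 1000 * agg$volume_L / agg$pig_count
  i <- match(format(b$clean$timestamp, "%Y-%m-%d %H"),
             format(agg$timestamp, "%Y-%m-%d %H"))
  raw_on_grid <- cons[i]
  differs <- is.na(raw_on_grid) |
    abs(raw_on_grid - b$clean$consumption) > 1e-9 * (1 + abs(b$clean$consumption))
  expect_setequal(format(b$clean$timestamp[differs], "%Y-%m-%d %H"),
                  format(b$ledger$hour, "%Y-%m-%d %H"))
})

test_that("farm-realistic clean series is non-negative and provenance-stamped", {
  b <- simulate_batch(batch_config(duration_weeks = 3, seed = 21))
  expect_true(all(b$clean$consumption >= 0))
  expect_equal(b$provenance$seed, 21L)
  expect_identical(b$provenance$mode, "farm-realistic")
  # bit-identical reruns under the same seed
  b2 <- simulate_batch(batch_config(duration_weeks = 3, seed = 21))
  expect_identical(b$raw, b2$raw)
  expect_identical(b$clean, b2$clean)
})
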