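# Residual diagnostics and descriptive analyses.

test_that("Ljung-Box matches the reference implementation and df convention", {
  set.seed(81)
  x <- rnorm(500)
  lb <- ljung_box(x, lags = 24)
  ref <- Box.test(x, lag = 24, type = "Ljung-Box")
  expect_equal(lb$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(lb$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(lb$df, 24)
  lb2 <- ljung_box(x, lags = 24, fitdf = 10)
  expect_equal(lb2$df, 14)
  expect_error(ljung_box(rep(1, 100)), "constant")
})

test_that("Ljung-Box has nominal size on white noise and power on AR(1)", {
  set.seed(82)
  rej <- vapply(1:1000, function(i)
    ljung_box(rnorm(500), lags = 24)$p_value < 0.05, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)

  pow <- vapply(1:200, function(i) {
    y <- simulate_armax(armax_spec(1, 0, ar_lags = 1),
                        armax_params(phi = c(`1` = 0.6)), n = 500,
                        seed = 8200 + i)
    ljung_box(y, lags = 24)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(pow), 0.99)
})

test_that("Ljung-Box p-values are near-uniform on fitted-model residuals", {
  set.seed(83)
  pv <- vapply(1:100, function(i) {
    y <- simulate_armax(armax_spec(1, 0, ar_lags = 1),
                        armax_params(phi = c(`1` = 0.5)), n = 400,
                        seed = 8300 + i)
    f <- fit_ml(armax_spec(1, 0, ar_lags = 1), y, hessian = FALSE)
    ljung_box(f$residuals, lags = 10)$p_value
  }, numeric(1))
  ks <- max(abs(sort(pv) - (1:100) / 100))
  expect_lt(ks, 0.15)
})

test_that("Shapiro-Wilk wrapper is calibrated, powered and subsampled", {
  set.seed(84)
  rej <- vapply(1:1000, function(i) shapiro_wilk(rnorm(500))$p_value < 0.05,
                logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)

  pow <- vapply(1:200, function(i) shapiro_wilk(rnorm(500)^2)$p_value < 0.01,
                logical(1))
  expect_gte(mean(pow), 0.99)

  out <- shapiro_wilk(rnorm(8000), max_n = 5000, seed = 2)
  expect_equal(out$n_used, 5000)
  expect_lte(out$W, 1)
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
})

test_that("hourly profiles aggregate by hour with the hot/cold calendar rule", {
  t0 <- as.POSIXct("2021-04-30 00:00:00", tz = "UTC")
  s <- data.frame(timestamp = t0 + 3600 * (0:47),
                  consumption = 7)
  pr <- hourly_profile(s)
  expect_equal(nrow(pr), 24)
  expect_equal(pr$mean, rep(7, 24))
  expect_equal(pr$sd, rep(0, 24))
  expect_equal(sum(pr$n), 48)
  # April 30 is cold, May 1 is hot
  expect_equal(sum(hourly_profile(s, "cold")$n), 24)
  expect_equal(sum(hourly_profile(s, "hot")$n), 24)
  expect_error(hourly_profile(s[1:10, ], "hot"), "season filter")

  # count-weighted seasonal means reproduce the all-season means exactly
  set.seed(85)
  s2 <- data.frame(timestamp = t0 + 3600 * (0:999),
                   consumption = runif(1000, 0, 300))
  all <- hourly_profile(s2); hot <- hourly_profile(s2, "hot")
  cold <- hourly_profile(s2, "cold")
  wmean <- (ifelse(is.na(hot$mean), 0, hot$mean) * hot$n +
              ifelse(is.na(cold$mean), 0, cold$mean) * cold$n) / (hot$n + cold$n)
  expect_equal(wmean, all$mean, tolerance = 1e-12)
})

test_that("generator batches show morning and late-afternoon profile peaks", {
  b <- simulate_batch(batch_config(duration_weeks = 6, seed = 29,
                                   corruption = no_corruption()))
  pr <- hourly_profile(b$clean)
  peaks <- pr$hour[which(diff(sign(diff(pr$mean))) == -2) + 1]
  expect_true(any(peaks >= 8 & peaks <= 12))
  expect_true(any(peaks >= 16 & peaks <= 17))
})

test_that("hour-of-day ANOVA has the right df, size and power", {
  t0 <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  set.seed(86)
  s <- data.frame(timestamp = t0 + 3600 * (0:479), consumption = rnorm(480))
  an <- hour_anova(s)
  expect_equal(an$df1, 23)
  expect_equal(an$df2, 480 - 24)

  rej <- vapply(1:400, function(i) {
    s$consumption <- rnorm(480)
    hour_anova(s)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.025)
  expect_lte(mean(rej), 0.075)

  b <- simulate_batch(batch_config(duration_weeks = 2, seed = 30,
                                   corruption = no_corruption()))
  expect_lt(hour_anova(b$clean)$p_value, 0.001)
  expect_error(hour_anova(s[1, , drop = FALSE]), "at least two hours")
})

test_that("harmonic overlay components sum to the design-matrix predictor", {
  co <- c(S1 = -0.75, S2 = -0.42, C1 = -0.74, C2 = -0.20)
  ov <- harmonic_overlay(co)
  H <- harmonic_design(0:23, 2)
  expect_equal(ov$total, as.vector(H[, names(co)] %*% co), tolerance = 1e-12)
  expect_equal(ov$H1, as.vector(H[, c("S1", "C1")] %*% co[c("S1", "C1")]),
               tolerance = 1e-12)

  flat <- harmonic_overlay(c(S1 = 0, C1 = 0))
  expect_equal(flat$total, rep(0, 24))

  single <- harmonic_overlay(c(C1 = 2.5))
  expect_equal(max(single$total), 2.5)
  expect_equal(single$hour[which.max(single$total)], 0)
})
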