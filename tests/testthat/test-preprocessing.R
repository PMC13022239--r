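# Cleaning rules: usage filtering, hourly aggregation, per-pig
# normalization, outlier exclusion, train/test partitioning.

test_that("hourly aggregation sums sub-readings and flags short hours", {
  rd <- flat_readings(2)
  rd$volume_L <- c(1, 2, 3, 4, 5, 6)
  agg <- aggregate_hourly(rd)
  expect_equal(agg$volume_L, c(6, 15))
  expect_false(any(agg$missing))
  # one absent sub-reading flags the hour missing
  agg2 <- aggregate_hourly(rd[-2, ])
  expect_true(agg2$missing[1])
  expect_true(is.na(agg2$volume_L[1]))
  expect_false(agg2$missing[2])
})

test_that("hourly aggregation matches a brute-force group-and-sum", {
  set.seed(31)
  rd <- flat_readings(50)
  rd$volume_L <- runif(nrow(rd), 0, 2)
  agg <- aggregate_hourly(rd)
  brute <- tapply(rd$volume_L, format(trunc(rd$timestamp, "hours"), "%Y-%m-%d %H"), sum)
  expect_equal(agg$volume_L,
               as.vector(brute[format(agg$timestamp, "%Y-%m-%d %H")]))
})

test_that("duplicate readings for one interval are an error naming it", {
  rd <- flat_readings(2)
  rd2 <- rbind(rd, rd[4, ])
  expect_error(aggregate_hourly(rd2), "duplicate reading.*01:00:00")
})

test_that("usage filtering keeps drinking only and reports the fraction", {
  rd <- flat_readings(4)
  rd$usage[1:2] <- "cooling"
  out <- filter_usage_type(rd)
  expect_equal(nrow(out$readings), 10)
  expect_equal(out$removed, 2)
  expect_equal(out$fraction, 2 / 12)
  expect_true(all(out$readings$usage == "drinking"))

  all_clean <- transform(rd, usage = "cleaning")
  expect_warning(out2 <- filter_usage_type(all_clean), "no drinking")
  expect_equal(nrow(out2$readings), 0)
  expect_error(filter_usage_type(transform(rd, usage = "garden")),
               "unknown usage type: garden")
})

test_that("generator defaults put the non-drinking share near 7.4 percent", {
  b <- simulate_batch(batch_config(duration_weeks = 6, seed = 17))
  out <- filter_usage_type(b$raw)
  expect_lt(abs(out$fraction - 0.074), 0.01)
})

test_that("per-pig normalization is 1000 * total / count with unpaired NA", {
  expect_equal(normalize_per_pig(69, 690), 100)
  expect_true(is.na(normalize_per_pig(5, 0)))
  expect_true(is.na(normalize_per_pig(5, NA)))
  v <- runif(10, 0, 8); p <- sample(600:700, 10)
  expect_equal(normalize_per_pig(v, p) * p / 1000, v, tolerance = 1e-12)
})

test_that("outlier rule removes strictly beyond 10 L/pig/h and negatives", {
  s <- data.frame(consumption = c(10001, 9999, 10000, -5, 120),
                  missing = FALSE)
  out <- remove_outliers(s)
  expect_equal(out$n_extreme, 1)
  expect_equal(out$n_negative, 1)
  expect_equal(out$series$consumption, c(NA, 9999, 10000, NA, 120))
  expect_equal(out$series$missing, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_error(remove_outliers(s, threshold = 0), "positive")
  # idempotence: re-cleaning changes nothing
  expect_identical(remove_outliers(out$series)$series, out$series)
})

test_that("cleaning report accounts for every hourly record exactly once", {
  b <- simulate_batch(batch_config(duration_weeks = 4, seed = 19))
  cs <- clean_series(b$raw, covariates = b$covariates)
  rep <- cs$report
  hour_rules <- rep$removed[rep$rule != "usage_type"]
  expect_equal(sum(hour_rules) + attr(rep, "retained"), nrow(cs$series))
  expect_true(all(rep$fraction >= 0 & rep$fraction <= 1))
  # retained values respect the cleaned-range invariant
  kept <- cs$series$consumption[!cs$series$missing]
  expect_true(all(kept >= 0 & kept <= 10000))
})

test_that("cleaning removes exactly the injected negative/extreme faults", {
  b <- simulate_batch(batch_config(duration_weeks = 4, seed = 23))
  cs <- clean_series(b$raw, covariates = b$covariates)
  agg <- aggregate_hourly(filter_usage_type(b$raw)$readings)
  cons <- normalize_per_pig(agg$volume_L, agg$pig_count)
  flagged_neg <- format(agg$timestamp[!is.na(cons) & cons < 0], "%Y-%m-%d %H")
  flagged_ext <- format(agg$timestamp[!is.na(cons) & cons > 10000], "%Y-%m-%d %H")
  led_neg <- format(b$ledger$hour[b$ledger$kind == "negative"], "%Y-%m-%d %H")
  led_ext <- format(b$ledger$hour[b$ledger$kind == "extreme"], "%Y-%m-%d %H")
  expect_setequal(flagged_neg, led_neg)   # precision = recall = 1
  expect_setequal(flagged_ext, led_ext)
})

test_that("train/test split holds out the last batch of every barn", {
  mk <- function(barn, batch, t0) {
    data.frame(timestamp = t0 + 3600 * (0:5), barn_id = barn, batch_id = batch,
               consumption = 1, missing = FALSE)
  }
  t0 <- as.POSIXct("2021-01-01", tz = "UTC")
  series <- list()
  for (b in 1:6) for (k in 1:5)
    series[[paste(b, k)]] <- mk(paste0("barn", b), as.character(k),
                                t0 + k * 86400 * 120)
  sp <- split_train_test(series)
  expect_length(sp$train, 24)
  expect_length(sp$test, 6)
  key <- function(s) paste(s$barn_id[1], s$batch_id[1])
  expect_length(intersect(vapply(sp$train, key, ""),
                          vapply(sp$test, key, "")), 0)
  expect_true(all(vapply(sp$test, function(s) s$batch_id[1], "") == "5"))

  small <- series[vapply(series, function(s)
    s$barn_id[1] %in% c("barn1", "barn2") && s$batch_id[1] %in% c("1", "2", "3"), TRUE)]
  sp2 <- split_train_test(small)
  expect_length(sp2$train, 4)
  expect_length(sp2$test, 2)

  expect_error(split_train_test(series[c("1 1", "2 1")]), "all-train")
  sp3 <- split_train_test(series[c("1 1", "2 1")], policy = "all-train")
  expect_length(sp3$train, 2)
  expect_length(sp3$test, 0)
})
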