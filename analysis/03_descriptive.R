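#!/usr/bin/env Rscript
# Step 3 — descriptive analysis of the drinking pattern.
#
# Daily intake range over the fattening period, the hourly consumption
# profile with its morning and late-afternoon peaks, the hot/cold seasonal
# split (May-October vs November-April), the hour-of-day ANOVA, and an OLS
# harmonic decomposition of the daily cycle (four sine/cosine pairs of the
# 24-h period) for overlay plotting.
#
# Reads results/cleaned_series.csv, writes results/descriptive_*.csv and a
# short text summary.

library(pigwater)

series <- read.csv(file.path("results", "cleaned_series.csv"),
                   stringsAsFactors = FALSE)
series$timestamp <- as.POSIXct(series$timestamp, tz = "UTC")

# daily intake per pig (L/pig/day), batch-wise
key <- paste(series$barn_id, series$batch_id)
daily <- aggregate(consumption ~ fattening_day + key,
                   data = cbind(series, key), FUN = sum)
daily$consumption <- daily$consumption / 1000
rng <- aggregate(consumption ~ fattening_day, data = daily, FUN = mean)
message(sprintf("daily intake: %.2f L/pig/day (first week) to %.2f (peak 7-day mean)",
                mean(rng$consumption[rng$fattening_day <= 7]),
                max(stats::filter(rng$consumption, rep(1/7, 7), sides = 2),
                    na.rm = TRUE)))

profiles <- rbind(
  cbind(season = "all", hourly_profile(series, "all")),
  cbind(season = "hot", hourly_profile(series, "hot")),
  cbind(season = "cold", hourly_profile(series, "cold")))
write.csv(profiles, file.path("results", "descriptive_hourly_profile.csv"),
          row.names = FALSE)

an <- hour_anova(series)
message(sprintf("hour-of-day ANOVA: F(%d, %d) = %.1f, p = %.3g",
                an$df1, an$df2, an$F, an$p_value))

# harmonic decomposition of the profile by OLS on the design columns
X <- build_design(series, n_harmonics = 4, covariates = character())
ok <- !is.na(series$consumption)
fit <- lm(series$consumption[ok] ~ X[ok, ])
co <- coef(fit)[-1]
names(co) <- colnames(X)
ov <- harmonic_overlay(co)
ov$mean_level <- coef(fit)[1]
write.csv(ov, file.path("results", "descriptive_harmonics.csv"), row.names = FALSE)

writeLines(c(
  sprintf("daily intake first week: %.2f L/pig/day",
          mean(rng$consumption[rng$fattening_day <= 7])),
  sprintf("peak 7-day mean: %.2f L/pig/day",
          max(stats::filter(rng$consumption, rep(1/7, 7), sides = 2), na.rm = TRUE)),
  sprintf("profile peak hours: %s",
          paste(profiles$hour[profiles$season == "all"][
            order(-profiles$mean[profiles$season == "all"])[1:3]], collapse = ", ")),
  sprintf("hour-of-day ANOVA: F(%d, %d) = %.1f, p = %.3g",
          an$df1, an$df2, an$F, an$p_value),
  "harmonic coefficients (mL/pig/h):",
  capture.output(print(round(co, 3)))),
  file.path("results", "descriptive_summary.txt"))
message("wrote results/descriptive_*.csv")
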