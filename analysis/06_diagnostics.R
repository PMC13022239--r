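#!/usr/bin/env Rscript
# Step 6 — model checking.
#
# Residual adequacy of the fitted model: Ljung-Box at lag 24 (df = 24),
# Shapiro-Wilk on (subsampled) residuals, residual-vs-fitted pairs for
# plotting, and the residual correlogram.
#
# Reads results/fit_state.rds, writes results/diagnostics.txt,
# results/residuals.csv and results/residual_correlogram.csv.

library(pigwater)

fit <- readRDS(file.path("results", "fit_state.rds"))$fit

lb <- ljung_box(fit$residuals, lags = 24)
sw <- shapiro_wilk(fit$residuals)
res <- fit$std_residuals

lines <- c(
  sprintf("Ljung-Box: Q = %.2f, df = %d, p = %.3f", lb$statistic, lb$df, lb$p_value),
  sprintf("Shapiro-Wilk: W = %.4f, p = %.3g (n used = %d)", sw$W, sw$p_value, sw$n_used),
  sprintf("standardized residuals: mean %.3f, sd %.3f",
          mean(res, na.rm = TRUE), sd(res[!is.na(res)])))
writeLines(lines, file.path("results", "diagnostics.txt"))
message(paste(lines, collapse = "\n"))

write.csv(data.frame(residual = fit$residuals, fitted = fit$fitted,
                     standardized = res),
          file.path("results", "residuals.csv"), row.names = FALSE)
cg <- correlogram(fit$residuals, 48)
write.csv(data.frame(lag = cg$lag, acf = cg$acf,
                     pacf = c(NA, cg$pacf), band = cg$band),
          file.path("results", "residual_correlogram.csv"), row.names = FALSE)
message("wrote results/diagnostics.txt, residuals.csv, residual_correlogram.csv")
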