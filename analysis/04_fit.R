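#!/usr/bin/env Rscript
# Step 4 — fit the subset ARMAX model.
#
# Holds out the last batch of every barn, stacks the remaining series with
# missing-hour separators, builds the 11-column design (4 harmonic pairs,
# outside temperature, ammonia, fattening day), and fits the subset
# ARMAX(24, 24) with active AR/MA lags {1, 2, 22, 23, 24} by CSS-initialized
# exact maximum likelihood.  Non-significant terms (Wald p > 0.05) are then
# fixed to zero and the reduced model refitted.
#
# Reads results/cleaned_series.csv, writes results/model_coefficients.csv
# and results/model_report.txt.

library(pigwater)

series <- read.csv(file.path("results", "cleaned_series.csv"),
                   stringsAsFactors = FALSE)
series$timestamp <- as.POSIXct(series$timestamp, tz = "UTC")
per_batch <- split(series, paste(series$barn_id, series$batch_id, sep = "\r"))

sp <- split_train_test(unname(per_batch))
message(sprintf("train/test: %d / %d series", length(sp$train), length(sp$test)))

Xl <- lapply(sp$train, build_design)
stacked <- pigwater:::stack_series(sp$train, Xl, gap_hours = 72)

spec <- armax_spec(24, 24, ar_lags = c(1, 2, 22, 23, 24),
                   ma_lags = c(1, 2, 22, 23, 24),
                   regressors = colnames(stacked$X))
message(sprintf("fitting subset ARMAX(24,24), %d free coefficients on %d hours ...",
                n_coef(spec), sum(!is.na(stacked$y))))
t0 <- proc.time()
fit <- fit_ml(spec, stacked$y, stacked$X)
message(sprintf("done in %.0f s; logLik %.1f, AIC %.1f, AICc %.1f, BIC %.1f",
                (proc.time() - t0)[3], fit$loglik, fit$aic, fit$aicc, fit$bic))

if (all(is.finite(fit$se))) {
  pruned_spec <- prune_coefficients(fit, alpha = 0.05)
  if (!identical(pruned_spec, spec)) {
    dropped <- setdiff(names(fit$coefficients),
                       names(pigwater:::pack_params(fit$estimates, pruned_spec)))
    message("pruned (p > 0.05): ", paste(dropped, collapse = ", "))
    fit <- fit_ml(pruned_spec, stacked$y, stacked$X)
    message(sprintf("refit: logLik %.1f, AIC %.1f", fit$loglik, fit$aic))
  } else {
    message("all terms significant at 0.05; nothing pruned")
  }
} else {
  message("standard errors unavailable (boundary/ill-conditioned information); pruning skipped")
}

w <- if (all(is.finite(fit$se))) wald_tests(fit) else
  data.frame(term = names(fit$coefficients),
             description = pigwater:::term_description(names(fit$coefficients)),
             estimate = unname(fit$coefficients),
             se = NA_real_, z = NA_real_, p_value = NA_real_)
w$sigma <- sqrt(fit$estimates$sigma2)
write.csv(w, file.path("results", "model_coefficients.csv"), row.names = FALSE)
writeLines(capture.output(print(fit)), file.path("results", "model_report.txt"))
saveRDS(list(fit = fit, test = sp$test), file.path("results", "fit_state.rds"))
print(w[, c("term", "estimate", "se", "z", "p_value")], digits = 3)
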