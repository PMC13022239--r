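# End-to-end orchestration: simulate -> clean -> design -> fit -> prune ->
# diagnose -> forecast, with every artifact written as delimited or
# structured text and every stochastic step seeded.  Thin numbered drivers
# under analysis/ call the same entry points.

#' Default pipeline configuration
#'
#' A plain list (round-trips through YAML unchanged) whose defaults mirror
#' the final barn analysis: 6 barns x 5 batches of 15 weeks, cleaning
#' threshold 10 L/pig/h, four harmonics, temperature/ammonia/fattening-day
#' covariates, subset ARMA lags \{1, 2, 22, 23, 24\}, pruning at alpha 0.05,
#' 95 percent intervals, lag-24 diagnostics.  Tests and examples shrink the
#' layout via the arguments.
#'
#' @param n_barns,n_batches,duration_weeks farm layout.
#' @param mode generator mode.
#' @param corruption_preset `"default"` or `"none"`.
#' @param ar_lags,ma_lags active lag sets of the fitted subset model.
#' @param covariates design covariates.
#' @param n_harmonics harmonic pairs.
#' @param threshold cleaning threshold (mL/pig/h).
#' @param prune_alpha Wald pruning level (NULL disables pruning).
#' @param level prediction-interval coverage.
#' @param lb_lags Ljung-Box pooling lags.
#' @param forecast_mode `"onestep"` or `"multistep"`.
#' @param split_policy `"last-batch"` or `"all-train"`.
#' @param gap_hours missing-hour separator inserted between concatenated
#'   training series.
#' @param seed master seed.
#' @return named list.
#' @export
run_config <- function(n_barns = 6, n_batches = 5, duration_weeks = 15,
                       mode = "farm-realistic",
                       corruption_preset = "default",
                       ar_lags = c(1, 2, 22, 23, 24),
                       ma_lags = c(1, 2, 22, 23, 24),
                       covariates = c("T", "NH3", "N"),
                       n_harmonics = 4,
                       threshold = 10000,
                       prune_alpha = 0.05,
                       level = 0.95, lb_lags = 24,
                       forecast_mode = "onestep",
                       split_policy = "last-batch",
                       gap_hours = 72,
                       seed = 1) {
  list(n_barns = n_barns, n_batches = n_batches,
       duration_weeks = duration_weeks, mode = mode,
       corruption_preset = corruption_preset,
       ar_lags = as.integer(ar_lags), ma_lags = as.integer(ma_lags),
       covariates = covariates, n_harmonics = as.integer(n_harmonics),
       threshold = threshold, prune_alpha = prune_alpha,
       level = level, lb_lags = as.integer(lb_lags),
       forecast_mode = forecast_mode, split_policy = split_policy,
       gap_hours = as.integer(gap_hours), seed = as.integer(seed))
}

validate_run_config <- function(config) {
  defaults <- run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  stopifnot(config$n_barns >= 1, config$n_batches >= 1,
            config$duration_weeks > 0, config$threshold > 0,
            config$level > 0, config$level < 1)
  if (!config$mode %in% c("farm-realistic", "model-truth"))
    stop("mode must be farm-realistic or model-truth")
  if (!config$forecast_mode %in% c("onestep", "multistep"))
    stop("forecast_mode must be onestep or multistep")
  if (!config$corruption_preset %in% c("default", "none"))
    stop("corruption_preset must be default or none")
  config
}

#' Read / write a pipeline configuration as YAML
#' @param path file path.
#' @param config a [run_config()] list.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(validate_run_config(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) validate_run_config(yaml::read_yaml(path))

# concatenate training series with missing-hour separators so the filter's
# prediction variance re-opens between independent batches
stack_series <- function(series_list, X_list, gap_hours) {
  ys <- list(); Xs <- list()
  k <- ncol(X_list[[1]])
  gapX <- matrix(NA_real_, gap_hours, k, dimnames = list(NULL, colnames(X_list[[1]])))
  for (i in seq_along(series_list)) {
    ys[[length(ys) + 1]] <- series_list[[i]]$consumption
    Xs[[length(Xs) + 1]] <- X_list[[i]]
    if (i < length(series_list)) {
      ys[[length(ys) + 1]] <- rep(NA_real_, gap_hours)
      Xs[[length(Xs) + 1]] <- gapX
    }
  }
  y <- unlist(ys, use.names = FALSE)
  X <- do.call(rbind, Xs)
  # the likelihood skips missing y; missing X rows only occur in the gaps
  X[is.na(X)] <- 0
  list(y = y, X = X)
}

#' Run the full analysis pipeline
#'
#' simulate -> clean -> split -> design -> CSS/ML fit -> Wald prune + refit ->
#' residual diagnostics -> held-out forecasting.  All artifacts are written
#' under `out_dir` as delimited or structured text with the seed recorded;
#' identical configurations produce byte-identical artifacts.
#'
#' @param config a [run_config()] list (missing fields take defaults).
#' @param out_dir output directory (created).
#' @return invisibly, a list with the fitted model, diagnostics, forecast
#'   scores and artifact paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage ", name, ": ",
                                     conditionMessage(e))),
                 file.path(out_dir, "log.txt"))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  corruption <- if (config$corruption_preset == "none") no_corruption() else corruption_rates()

  # -- simulate ---------------------------------------------------------------
  batches <- stage("simulate", {
    say("simulate: %d barns x %d batches (%s, %d weeks, seed %d)",
        config$n_barns, config$n_batches, config$mode,
        config$duration_weeks, config$seed)
    simulate_farm(config$n_barns, config$n_batches, seed = config$seed,
                  mode = config$mode, duration_weeks = config$duration_weeks,
                  corruption = corruption)
  })

  # -- preprocess -------------------------------------------------------------
  cleaned <- stage("preprocess", {
    out <- lapply(batches, function(b)
      clean_series(b$raw, covariates = b$covariates,
                   threshold = config$threshold))
    reports <- lapply(out, `[[`, "report")
    agg <- Reduce(function(a, b) {
      a$removed <- a$removed + b$removed; a$total <- a$total + b$total; a
    }, reports)
    agg$fraction <- agg$removed / agg$total
    attr(agg, "retained") <- sum(vapply(reports, attr, 0, "retained"))
    series <- lapply(out, `[[`, "series")
    all_series <- do.call(rbind, series)
    write.csv(all_series, file.path(out_dir, "cleaned_series.csv"),
              row.names = FALSE)
    rep_txt <- utils::capture.output(print(agg))
    writeLines(rep_txt, file.path(out_dir, "cleaning_report.txt"))
    for (r in seq_len(nrow(agg)))
      say("clean: rule %-14s removed %7d of %8d (%.2f%%)",
          agg$rule[r], agg$removed[r], agg$total[r], 100 * agg$fraction[r])
    list(series = series, report = agg)
  })

  # -- split + design ---------------------------------------------------------
  parts <- stage("split", {
    sp <- split_train_test(cleaned$series, config$split_policy)
    say("split: %d train / %d test series", length(sp$train), length(sp$test))
    sp
  })
  design <- stage("design", {
    Xl <- lapply(parts$train, build_design, n_harmonics = config$n_harmonics,
                 covariates = config$covariates)
    stack_series(parts$train, Xl, config$gap_hours)
  })

  # -- fit + prune ------------------------------------------------------------
  fit <- stage("fit", {
    spec <- armax_spec(p = max(config$ar_lags, 0), q = max(config$ma_lags, 0),
                       ar_lags = config$ar_lags, ma_lags = config$ma_lags,
                       regressors = colnames(design$X))
    say("fit: subset ARMAX(%d, %d), %d free coefficients, %d training hours",
        spec$p, spec$q, n_coef(spec), sum(!is.na(design$y)))
    f <- fit_ml(spec, design$y, design$X)
    if (any(!is.finite(f$se))) {
      say("fit: standard errors unavailable (boundary or ill-conditioned information); pruning skipped")
      config$prune_alpha <- NULL
    }
    if (!is.null(config$prune_alpha)) {
      sp2 <- prune_coefficients(f, alpha = config$prune_alpha)
      if (!identical(sp2, spec)) {
        dropped <- setdiff(names(pack_params(f$estimates, spec)),
                           names(pack_params(f$estimates, sp2)))
        say("prune: dropped %s; refitting", paste(dropped, collapse = ", "))
        f2 <- fit_ml(sp2, design$y, design$X)
        attr(f2, "pruned_terms") <- dropped
        f <- f2
      } else say("prune: all terms significant at alpha = %g", config$prune_alpha)
    }
    w <- if (all(is.finite(f$se))) wald_tests(f) else
      data.frame(term = names(f$coefficients),
                 description = term_description(names(f$coefficients)),
                 estimate = unname(f$coefficients),
                 se = NA_real_, z = NA_real_, p_value = NA_real_)
    write.csv(cbind(w, data.frame(sigma2 = f$estimates$sigma2,
                                  loglik = f$loglik, aic = f$aic,
                                  aicc = f$aicc, bic = f$bic)[rep(1, nrow(w)), ]),
              file.path(out_dir, "coefficients.csv"), row.names = FALSE)
    writeLines(utils::capture.output(print(f)),
               file.path(out_dir, "model_report.txt"))
    f
  })

  # -- diagnostics ------------------------------------------------------------
  diag <- stage("diagnose", {
    res <- fit$std_residuals
    lb <- ljung_box(fit$residuals, lags = config$lb_lags)
    sw <- shapiro_wilk(fit$residuals)
    all_train <- do.call(rbind, parts$train)
    an <- hour_anova(all_train)
    lines <- c(
      sprintf("Ljung-Box: Q = %.4f, df = %d, p = %.4f", lb$statistic, lb$df, lb$p_value),
      sprintf("Shapiro-Wilk: W = %.4f, p = %.4g (n used = %d)", sw$W, sw$p_value, sw$n_used),
      sprintf("Hour-of-day ANOVA: F(%d, %d) = %.2f, p = %.4g", an$df1, an$df2, an$F, an$p_value),
      sprintf("Residuals: mean %.4f, sd %.4f", mean(res, na.rm = TRUE), sd(res[!is.na(res)])))
    writeLines(lines, file.path(out_dir, "diagnostics.txt"))
    for (l in lines) say("diagnose: %s", l)
    list(ljung_box = lb, shapiro_wilk = sw, anova = an)
  })

  # -- forecast ---------------------------------------------------------------
  fc <- stage("forecast", {
    if (!length(parts$test)) {
      writeLines("forecast: not evaluated (empty test set)",
                 file.path(out_dir, "forecast.csv"))
      say("forecast: not evaluated (empty test set)")
      NULL
    } else {
      rows <- list(); scores <- list()
      for (s in parts$test) {
        Xs <- build_design(s, n_harmonics = config$n_harmonics,
                           covariates = config$covariates)
        Xs[is.na(Xs)] <- 0
        if (config$forecast_mode == "onestep") {
          f1 <- one_step_forecasts(fit$spec, fit$estimates, s$consumption, Xs,
                                   level = config$level)
        } else {
          n0 <- floor(nrow(s) / 2)
          ll <- exact_loglik(fit$spec, fit$estimates,
                             s$consumption[seq_len(n0)],
                             Xs[seq_len(n0), , drop = FALSE])
          h <- nrow(s) - n0
          f1 <- forecast_h(structure(list(spec = fit$spec,
                                          estimates = fit$estimates,
                                          filter_state = attr(ll, "state")),
                                     class = "armax_fit"),
                           h, Xs[(n0 + 1):nrow(s), , drop = FALSE],
                           level = config$level)
          f1$actual <- s$consumption[(n0 + 1):nrow(s)]
          f1$std_error <- (f1$actual - f1$forecast) / f1$se
        }
        key <- paste(s$barn_id[1], s$batch_id[1], sep = "/")
        f1$series <- key
        rows[[key]] <- f1
        scores[[key]] <- rmse(f1$forecast, f1$actual)
        say("forecast: %s RMSE = %.2f mL/pig/h", key, scores[[key]])
      }
      tab <- do.call(rbind, rows)
      write.csv(tab, file.path(out_dir, "forecast.csv"), row.names = FALSE)
      list(table = tab, rmse = unlist(scores))
    }
  })

  stage("provenance", {
    yaml::write_yaml(list(config = config,
                          package_version = as.character(utils::packageVersion("pigwater"))),
                     file.path(out_dir, "provenance.yaml"))
  })
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(fit = fit, diagnostics = diag, forecast = fc,
                 cleaning = cleaned$report, out_dir = out_dir,
                 artifacts = list.files(out_dir)))
}

#' Human-readable summary of a completed run directory
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
report_run <- function(run_dir) {
  needed <- c("cleaning_report.txt", "coefficients.csv", "model_report.txt",
              "diagnostics.txt", "forecast.csv", "provenance.yaml")
  present <- file.exists(file.path(run_dir, needed))
  if (!all(present))
    stop("incomplete run directory; missing: ",
         paste(needed[!present], collapse = ", "))
  co <- read.csv(file.path(run_dir, "coefficients.csv"))
  lines <- c("== Barn water-consumption model run ==", "",
             "-- Cleaning --", readLines(file.path(run_dir, "cleaning_report.txt")),
             "", "-- Coefficients (term, estimate, SE, z, p) --",
             utils::capture.output(print(co[, c("term", "estimate", "se", "z", "p_value")],
                                         row.names = FALSE, digits = 4)),
             sprintf("AIC %.2f  AICc %.2f  BIC %.2f", co$aic[1], co$aicc[1], co$bic[1]),
             "", "-- Diagnostics --", readLines(file.path(run_dir, "diagnostics.txt")),
             "", "-- Forecast --")
  fc_first <- readLines(file.path(run_dir, "forecast.csv"), n = 1)
  if (grepl("not evaluated", fc_first)) {
    lines <- c(lines, "not evaluated")
  } else {
    fc <- read.csv(file.path(run_dir, "forecast.csv"))
    for (key in unique(fc$series)) {
      sub <- fc[fc$series == key, ]
      lines <- c(lines, sprintf("%s: RMSE %.2f mL/pig/h over %d hours",
                                key, rmse(sub$forecast, sub$actual),
                                sum(!is.na(sub$actual))))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
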