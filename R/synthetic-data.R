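# Synthetic barn-data generator.  Two modes:
#   * "model-truth"    — the exact subset-ARMAX equation with the shipped
#                        coefficient set, for estimator validation;
#   * "farm-realistic" — calibrated descriptive patterns (logistic growth
#                        trend, two-peak diurnal shape, end-of-batch ramp-down,
#                        multiplicative ARMA noise) plus sensor corruption,
#                        for pipeline testing.
# Every stochastic component is seeded and all outputs carry provenance.

#' Barn environment configuration
#'
#' Parameters of the simulated outdoor/indoor climate: temperature is an
#' annual sinusoid (period 8760 h, peak mid-July) plus a diurnal sinusoid
#' (period 24 h, peak mid-afternoon) plus first-order autocorrelated noise;
#' ammonia couples negatively to temperature (ventilation opens in summer).
#'
#' @param annual_mean,annual_amplitude annual temperature mean and amplitude (degC).
#' @param diurnal_amplitude within-day temperature amplitude (degC).
#' @param noise_ar lag-1 autocorrelation of the temperature noise, in (-1, 1).
#' @param noise_sd marginal SD of the temperature noise (degC).
#' @param nh3_baseline ammonia baseline (ppm).
#' @param nh3_coupling ammonia change per degC of temperature anomaly
#'   (ppm/degC, expected negative).
#' @param nh3_sd ammonia noise SD (ppm).
#' @param humidity_baseline,humidity_sd relative humidity baseline and noise SD (percent).
#' @param co2_baseline,co2_sd carbon dioxide baseline and noise SD (ppm).
#' @return list of class `environment_config`.
#' @export
environment_config <- function(annual_mean = 13, annual_amplitude = 9,
                               diurnal_amplitude = 4,
                               noise_ar = 0.8, noise_sd = 1.5,
                               nh3_baseline = 18, nh3_coupling = -0.6,
                               nh3_sd = 2,
                               humidity_baseline = 65, humidity_sd = 8,
                               co2_baseline = 2000, co2_sd = 300) {
  vals <- c(annual_mean, annual_amplitude, diurnal_amplitude, noise_ar,
            noise_sd, nh3_baseline, nh3_coupling, nh3_sd,
            humidity_baseline, humidity_sd, co2_baseline, co2_sd)
  if (any(!is.finite(vals))) stop("non-finite environment configuration value")
  if (annual_amplitude < 0 || diurnal_amplitude < 0)
    stop("amplitudes must be non-negative")
  if (noise_sd < 0 || nh3_sd < 0 || humidity_sd < 0 || co2_sd < 0)
    stop("noise SDs must be non-negative")
  if (abs(noise_ar) >= 1) stop("noise autocorrelation must lie strictly inside (-1, 1)")
  structure(list(annual_mean = annual_mean, annual_amplitude = annual_amplitude,
                 diurnal_amplitude = diurnal_amplitude, noise_ar = noise_ar,
                 noise_sd = noise_sd, nh3_baseline = nh3_baseline,
                 nh3_coupling = nh3_coupling, nh3_sd = nh3_sd,
                 humidity_baseline = humidity_baseline, humidity_sd = humidity_sd,
                 co2_baseline = co2_baseline, co2_sd = co2_sd),
            class = "environment_config")
}

#' Simulate hourly environmental covariates
#'
#' @param n_hours number of hours (>= 1).
#' @param start first timestamp (POSIXct, UTC recommended).
#' @param cfg an [environment_config()].
#' @param seed integer seed; identical seed and config give bit-identical output.
#' @return data frame: `timestamp`, `temperature`, `temperature_noise` (the
#'   autocorrelated noise component alone), `nh3`, `humidity`, `co2`.
#' @export
simulate_environment <- function(n_hours,
                                 start = as.POSIXct("2021-01-01 00:00:00", tz = "UTC"),
                                 cfg = environment_config(), seed = 1) {
  stopifnot(inherits(cfg, "environment_config"), n_hours >= 1)
  set.seed(seed)
  ts <- start + 3600 * (seq_len(n_hours) - 1)
  doy <- as.numeric(format(ts, "%j")) + as.numeric(format(ts, "%H")) / 24
  hod <- as.numeric(format(ts, "%H"))
  annual <- cfg$annual_mean +
    cfg$annual_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  diurnal <- cfg$diurnal_amplitude * cos(2 * pi * (hod - 15) / 24)
  noise <- if (cfg$noise_sd > 0) {
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_ar^2)
    as.vector(stats::filter(rnorm(n_hours, sd = innov_sd), cfg$noise_ar,
                            method = "recursive"))
  } else rep(0, n_hours)
  temperature <- annual + diurnal + noise
  nh3 <- pmax(0, cfg$nh3_baseline +
                cfg$nh3_coupling * (temperature - cfg$annual_mean) +
                rnorm(n_hours, sd = cfg$nh3_sd))
  humidity <- pmin(100, pmax(0, cfg$humidity_baseline + rnorm(n_hours, sd = cfg$humidity_sd)))
  co2 <- pmax(0, cfg$co2_baseline + rnorm(n_hours, sd = cfg$co2_sd))
  data.frame(timestamp = ts, temperature = temperature,
             temperature_noise = noise, nh3 = nh3,
             humidity = humidity, co2 = co2)
}

#' Simulate the hourly pig count of a batch
#'
#' Each of the `n_start` pigs dies with probability `mortality_total` at a
#' time uniform over the batch, so the count is a non-increasing step function
#' with expected final value `n_start * (1 - mortality_total)`.
#'
#' @param n_start starting head count (>= 1).
#' @param mortality_total batch mortality fraction in [0, 1).
#' @param n_hours batch length in hours.
#' @param seed integer seed.
#' @return integer vector of length `n_hours`.
#' @export
simulate_pig_counts <- function(n_start, mortality_total = 0.0339, n_hours,
                                seed = 1) {
  stopifnot(n_start >= 1, mortality_total >= 0, mortality_total < 1, n_hours >= 1)
  set.seed(seed)
  n_deaths <- rbinom(1, n_start, mortality_total)
  counts <- rep.int(as.integer(n_start), n_hours)
  if (n_deaths > 0) {
    times <- sample.int(n_hours, n_deaths, replace = TRUE)
    counts <- as.integer(n_start - cumsum(tabulate(times, n_hours)))
  }
  counts
}

#' Calibration of the farm-realistic consumption surface
#'
#' The mean surface is `1000 * trend(day) * shape(hour)` mL/pig/h: a logistic
#' growth trend in fattening day calibrated to first-week and plateau daily
#' totals (L/pig/day), a two-peak diurnal shape (morning and late-afternoon
#' von-Mises bumps, near-zero overnight) normalized to sum to one over the 24
#' hours, and a linear ramp to zero over the final `ramp_days` of the batch.
#' Noise is multiplicative: relative subset-ARMA noise scaled by the surface.
#'
#' @param start_daily,end_daily first-week and plateau daily totals (L/pig/day).
#' @param midpoint_day,scale_days logistic trend midpoint and scale (days).
#' @param total_days batch length in days (15 weeks = 105).
#' @param ramp_days length of the end-of-batch linear ramp to zero.
#' @param rel_noise_sd relative SD of the multiplicative ARMA noise.
#' @param morning_peak,afternoon_peak bump centres (hour of day).
#' @param morning_conc,afternoon_conc bump concentrations (von-Mises kappa).
#' @param morning_weight mixture weight of the morning bump in (0, 1).
#' @return list of class `farm_calibration`.
#' @export
farm_calibration <- function(start_daily = 2.35, end_daily = 8.05,
                             midpoint_day = 55, scale_days = 12,
                             total_days = 105, ramp_days = 3,
                             rel_noise_sd = 0.2,
                             morning_peak = 9.5, afternoon_peak = 16.5,
                             morning_conc = 3, afternoon_conc = 3.5,
                             morning_weight = 0.32) {
  stopifnot(start_daily > 0, end_daily > 0, total_days > 0, ramp_days >= 0,
            rel_noise_sd >= 0, morning_weight > 0, morning_weight < 1)
  structure(list(start_daily = start_daily, end_daily = end_daily,
                 midpoint_day = midpoint_day, scale_days = scale_days,
                 total_days = total_days, ramp_days = ramp_days,
                 rel_noise_sd = rel_noise_sd,
                 morning_peak = morning_peak, afternoon_peak = afternoon_peak,
                 morning_conc = morning_conc, afternoon_conc = afternoon_conc,
                 morning_weight = morning_weight),
            class = "farm_calibration")
}

# diurnal shape: fraction of the daily total drunk in each clock hour
diurnal_shape <- function(hour, cal = farm_calibration()) {
  bump <- function(h, centre, conc) exp(conc * (cos(2 * pi * (h - centre) / 24) - 1))
  raw <- cal$morning_weight * bump(hour, cal$morning_peak, cal$morning_conc) +
    (1 - cal$morning_weight) * bump(hour, cal$afternoon_peak, cal$afternoon_conc)
  norm <- cal$morning_weight * sum(bump(0:23, cal$morning_peak, cal$morning_conc)) +
    (1 - cal$morning_weight) * sum(bump(0:23, cal$afternoon_peak, cal$afternoon_conc))
  raw / norm
}

# logistic growth trend with end-of-batch ramp, in L/pig/day; the raw
# logistic is affinely rescaled so that the mean over fattening days 1-7
# equals start_daily exactly and the asymptote equals end_daily
daily_trend <- function(day, cal = farm_calibration()) {
  raw <- function(d) stats::plogis((d - cal$midpoint_day) / cal$scale_days)
  r0 <- mean(raw(1:7))
  tr <- cal$start_daily + (cal$end_daily - cal$start_daily) *
    (raw(day) - r0) / (1 - r0)
  if (cal$ramp_days > 0) {
    ramp_start <- cal$total_days - cal$ramp_days
    f <- pmin(1, pmax(0, (cal$total_days - day) / cal$ramp_days))
    tr <- ifelse(day > ramp_start, tr * f, tr)
  }
  tr
}

#' Expected hourly consumption surface
#'
#' In `"model-truth"` mode, the linear predictor of the shipped subset-ARMAX
#' model: intercept + harmonic terms + regression effects of temperature,
#' ammonia and fattening day (may be negative; intended for estimator
#' validation only).  In `"farm-realistic"` mode, the non-negative calibrated
#' surface `1000 * trend(day) * shape(hour)` in mL/pig/h.
#'
#' @param hour_of_day integer hours 0-23 (vectorized).
#' @param fattening_day integer days since batch start, >= 1 (vectorized).
#' @param covariates for model-truth mode: a list or data frame with elements
#'   `T` (temperature, degC) and `NH3` (ammonia, ppm).
#' @param mode `"farm-realistic"` or `"model-truth"`.
#' @param params model-truth coefficient set (default [barn_truth_model()]).
#' @param calibration farm-realistic calibration ([farm_calibration()]).
#' @return expected consumption (mL/pig/h).
#' @export
mean_consumption_profile <- function(hour_of_day, fattening_day,
                                     covariates = NULL,
                                     mode = c("farm-realistic", "model-truth"),
                                     params = NULL,
                                     calibration = farm_calibration()) {
  mode <- match.arg(mode)
  if (mode == "model-truth") {
    if (is.null(params)) params <- barn_truth_model()$params
    if (is.null(covariates) || is.null(covariates$T) || is.null(covariates$NH3))
      stop("model-truth mode requires covariates T and NH3")
    eta <- params$eta
    H <- harmonic_design(hour_of_day, n_harmonics = 4)
    harm <- as.vector(H %*% eta[colnames(H)])
    params$mu + harm + eta[["T"]] * covariates$T +
      eta[["NH3"]] * covariates$NH3 + eta[["N"]] * fattening_day
  } else {
    1000 * daily_trend(fattening_day, calibration) *
      diurnal_shape(hour_of_day, calibration)
  }
}

#' Sensor-corruption rate configuration
#'
#' Per-hour injection rates for each fault kind, plus the rate at which
#' non-drinking (cooling/cleaning) usage records are interleaved, expressed
#' relative to the drinking record count.  Defaults place the combined
#' negative + extreme outlier rate at 0.0748 and the non-drinking share at
#' about 7.4 percent of total records.
#'
#' @param extreme fraction of hours receiving an extreme (> 10 L/pig/h) spike.
#' @param negative fraction of hours receiving a negative spike.
#' @param consecutive fraction of hours starting a doubled/zeroed hour pair.
#' @param missing fraction of hours losing one sub-hourly reading.
#' @param non_drinking cooling/cleaning records per drinking record.
#' @return list of class `corruption_rates`.
#' @export
corruption_rates <- function(extreme = 0.05, negative = 0.0248,
                             consecutive = 0.005, missing = 0.01,
                             non_drinking = 0.08) {
  r <- c(extreme, negative, consecutive, missing, non_drinking)
  if (any(r < 0 | r > 1)) stop("corruption rates must lie in [0, 1]")
  structure(list(extreme = extreme, negative = negative,
                 consecutive = consecutive, missing = missing,
                 non_drinking = non_drinking),
            class = "corruption_rates")
}

#' @rdname corruption_rates
#' @export
no_corruption <- function() corruption_rates(0, 0, 0, 0, 0)

#' Inject logged sensor faults into raw meter readings
#'
#' Injects (a) negative spikes driving the hourly total below zero, (b)
#' extreme spikes driving the hourly per-pig total above 10 L/pig/h by
#' construction, (c) consecutive-hour sums (one hour doubled, the next
#' zeroed), and (d) missing readings.  Fault hours are disjoint across kinds
#' and every injection is logged, so cleaning can be scored exactly.
#'
#' @param readings raw-readings data frame (`timestamp`, `barn_id`,
#'   `batch_id`, `usage`, `volume_L`, `pig_count`); only drinking records are
#'   touched.
#' @param rates a [corruption_rates()] (the `non_drinking` rate is ignored
#'   here — usage interleaving happens at generation time).
#' @param seed integer seed.
#' @return list with `readings` (corrupted) and `ledger` (data frame
#'   `barn_id`, `batch_id`, `hour`, `kind`).
#' @export
corrupt_readings <- function(readings, rates = corruption_rates(), seed = 1) {
  stopifnot(inherits(rates, "corruption_rates"))
  set.seed(seed)
  drink <- which(readings$usage == "drinking")
  hour_of <- as.POSIXct(trunc(readings$timestamp, "hours"))
  hours <- sort(unique(hour_of[drink]))
  n_h <- length(hours)
  empty_ledger <- data.frame(barn_id = character(), batch_id = character(),
                             hour = as.POSIXct(character()), kind = character())
  if (n_h == 0 || (rates$extreme == 0 && rates$negative == 0 &&
                   rates$consecutive == 0 && rates$missing == 0))
    return(list(readings = readings, ledger = empty_ledger))

  k_ext <- rbinom(1, n_h, rates$extreme)
  k_neg <- rbinom(1, n_h, rates$negative)
  k_con <- rbinom(1, n_h, rates$consecutive)
  k_mis <- rbinom(1, n_h, rates$missing)
  perm <- sample(hours)
  take <- function(k) {
    if (k == 0) return(as.POSIXct(character(), tz = attr(hours, "tzone")))
    out <- utils::head(perm, k)
    perm <<- utils::tail(perm, length(perm) - k)
    out
  }
  h_ext <- take(k_ext); h_neg <- take(k_neg); h_mis <- take(k_mis)
  # consecutive pairs need hour+1 untouched by any other fault
  h_con_cand <- take(k_con)
  keep_con <- logical(length(h_con_cand))
  for (i in seq_along(h_con_cand)) {
    h2 <- h_con_cand[i] + 3600
    if ((h2 %in% perm) || !(h2 %in% hours)) {
      keep_con[i] <- TRUE
      perm <- perm[perm != h2]
    }
  }
  h_con <- h_con_cand[keep_con]

  ledger <- list()
  log_fault <- function(h, kind) {
    i <- drink[hour_of[drink] == h][1]
    ledger[[length(ledger) + 1]] <<- data.frame(
      barn_id = readings$barn_id[i], batch_id = readings$batch_id[i],
      hour = h, kind = kind)
  }

  for (i in seq_along(h_ext)) {
    h <- h_ext[i]
    idx <- drink[hour_of[drink] == h]
    j <- sample(idx, 1)
    s_other <- sum(readings$volume_L[setdiff(idx, j)])
    pigs <- readings$pig_count[j]
    readings$volume_L[j] <- (10.05 + rexp(1)) * pigs - s_other
    log_fault(h, "extreme")
  }
  for (i in seq_along(h_neg)) {
    h <- h_neg[i]
    idx <- drink[hour_of[drink] == h]
    j <- sample(idx, 1)
    s_other <- sum(readings$volume_L[setdiff(idx, j)])
    pigs <- readings$pig_count[j]
    readings$volume_L[j] <- -s_other - (0.05 + rexp(1)) * pigs
    log_fault(h, "negative")
  }
  for (i in seq_along(h_con)) {
    h <- h_con[i]
    idx1 <- drink[hour_of[drink] == h]
    idx2 <- drink[hour_of[drink] == (h + 3600)]
    readings$volume_L[idx1] <- 2 * readings$volume_L[idx1]
    readings$volume_L[idx2] <- 0
    log_fault(h, "consecutive_double")
    log_fault(h + 3600, "consecutive_zero")
  }
  drop_rows <- integer()
  for (i in seq_along(h_mis)) {
    h <- h_mis[i]
    idx <- drink[hour_of[drink] == h]
    drop_rows <- c(drop_rows, sample(idx, 1))
    log_fault(h, "missing")
  }
  if (length(drop_rows)) readings <- readings[-drop_rows, ]
  ledger <- if (length(ledger)) do.call(rbind, ledger) else empty_ledger
  ledger <- ledger[order(ledger$hour), ]
  rownames(ledger) <- NULL
  list(readings = readings, ledger = ledger)
}

#' Batch simulation configuration
#'
#' @param start batch start (POSIXct).
#' @param duration_weeks fattening length (default 15).
#' @param n_start starting pig count (study range 660-730; default 690).
#' @param mortality_total batch mortality fraction (default 0.0339).
#' @param mode `"farm-realistic"` or `"model-truth"`.
#' @param barn_id,batch_id identifiers stamped on every record.
#' @param calibration a [farm_calibration()] (farm-realistic mode).
#' @param model list with `spec`/`params` (model-truth mode; default
#'   [barn_truth_model()]).
#' @param env an [environment_config()].
#' @param corruption a [corruption_rates()].
#' @param seed master seed; all component seeds derive from it.
#' @return list of class `batch_config`.
#' @export
batch_config <- function(start = as.POSIXct("2021-01-01 00:00:00", tz = "UTC"),
                         duration_weeks = 15, n_start = 690,
                         mortality_total = 0.0339,
                         mode = c("farm-realistic", "model-truth"),
                         barn_id = "B1", batch_id = "1",
                         calibration = farm_calibration(),
                         model = NULL,
                         env = environment_config(),
                         corruption = corruption_rates(),
                         seed = 1) {
  mode <- match.arg(mode)
  stopifnot(duration_weeks > 0, n_start >= 1,
            mortality_total >= 0, mortality_total < 1)
  structure(list(start = start, duration_weeks = duration_weeks,
                 n_start = n_start, mortality_total = mortality_total,
                 mode = mode, barn_id = as.character(barn_id),
                 batch_id = as.character(batch_id),
                 calibration = calibration, model = model, env = env,
                 corruption = corruption, seed = as.integer(seed)),
            class = "batch_config")
}

#' Simulate one barn x batch: clean ground truth and raw meter readings
#'
#' Builds the hourly covariate trace, pig counts and mean consumption surface,
#' adds subset-ARMA noise (exact equation in model-truth mode, multiplicative
#' relative noise in farm-realistic mode; 2000-step burn-in), splits the clean
#' hourly series into an exact 20-min reading cadence (3 readings/hour),
#' interleaves non-drinking usage records, and injects logged sensor faults.
#'
#' @param cfg a [batch_config()].
#' @return list of class `pig_batch`: `raw` (readings data frame), `clean`
#'   (hourly ground-truth series), `covariates` (hourly environment table),
#'   `ledger` (injected-fault log) and `provenance` (config, mode, seeds,
#'   truth parameters).
#' @export
simulate_batch <- function(cfg = batch_config()) {
  stopifnot(inherits(cfg, "batch_config"))
  n_hours <- as.integer(cfg$duration_weeks * 7 * 24)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 5)

  env <- simulate_environment(n_hours, start = cfg$start, cfg = cfg$env,
                              seed = seeds[1])
  pigs <- simulate_pig_counts(cfg$n_start, cfg$mortality_total, n_hours,
                              seed = seeds[2])
  ts <- env$timestamp
  hod <- as.integer(format(ts, "%H"))
  fday <- 1L + (seq_len(n_hours) - 1L) %/% 24L

  if (cfg$mode == "model-truth") {
    model <- if (is.null(cfg$model)) barn_truth_model() else cfg$model
    d <- params_dense(model$params, model$spec)
    assert_stationary(d$phi, d$theta)
    X <- cbind(harmonic_design(hod, 4),
               T = env$temperature, NH3 = env$nh3, N = as.numeric(fday))
    consumption <- simulate_armax(model$spec, model$params, X, n_hours,
                                  burn_in = 2000, seed = seeds[3])
    truth <- model
  } else {
    profile <- mean_consumption_profile(hod, fday, mode = "farm-realistic",
                                        calibration = cfg$calibration)
    if (cfg$calibration$rel_noise_sd > 0) {
      noise_model <- barn_truth_model()
      nspec <- armax_spec(noise_model$spec$p, noise_model$spec$q,
                          ar_lags = noise_model$spec$ar_lags,
                          ma_lags = noise_model$spec$ma_lags,
                          regressors = character(), intercept = FALSE)
      nparams <- armax_params(mu = 0, phi = noise_model$params$phi,
                              theta = noise_model$params$theta, sigma2 = 1)
      u <- simulate_armax(nspec, nparams, NULL, n_hours, burn_in = 2000,
                          seed = seeds[3])
      psi <- stats::ARMAtoMA(ar = full_lag_vector(nparams$phi, nspec$p),
                             ma = full_lag_vector(nparams$theta, nspec$q),
                             lag.max = 2000)
      u <- u / sqrt(1 + sum(psi^2))
      consumption <- pmax(0, profile * (1 + cfg$calibration$rel_noise_sd * u))
    } else {
      consumption <- profile
    }
    truth <- list(calibration = cfg$calibration)
  }

  clean <- data.frame(timestamp = ts, barn_id = cfg$barn_id,
                      batch_id = cfg$batch_id,
                      consumption = consumption, pig_count = pigs,
                      temperature = env$temperature, nh3 = env$nh3,
                      fattening_day = fday, missing = FALSE)

  # exact 20-min cadence: each hour split into three equal readings (litres)
  vol_hour_L <- consumption * pigs / 1000
  offs <- c(0, 1200, 2400)
  raw <- data.frame(
    timestamp = rep(ts, each = 3) + rep(offs, times = n_hours),
    barn_id = cfg$barn_id, batch_id = cfg$batch_id,
    usage = "drinking",
    volume_L = rep(vol_hour_L / 3, each = 3),
    pig_count = rep(pigs, each = 3))

  set.seed(seeds[4])
  if (cfg$corruption$non_drinking > 0) {
    n_nd <- round(cfg$corruption$non_drinking * nrow(raw))
    slots <- sample.int(nrow(raw), n_nd)
    nd <- data.frame(
      timestamp = raw$timestamp[slots],
      barn_id = cfg$barn_id, batch_id = cfg$batch_id,
      usage = sample(c("cooling", "cleaning"), n_nd, replace = TRUE),
      volume_L = rexp(n_nd, rate = 1 / 5),
      pig_count = raw$pig_count[slots])
    raw <- rbind(raw, nd)
    raw <- raw[order(raw$timestamp, raw$usage), ]
    rownames(raw) <- NULL
  }

  cr <- corrupt_readings(raw, cfg$corruption, seed = seeds[5])

  structure(list(raw = cr$readings, clean = clean, covariates = env,
                 ledger = cr$ledger,
                 provenance = list(config = cfg, mode = cfg$mode,
                                   seed = cfg$seed, component_seeds = seeds,
                                   truth = truth)),
            class = "pig_batch")
}

#' Simulate a set of barns and batches
#'
#' Convenience wrapper reproducing the study layout (6 barns x 5 batches = 30
#' series by default); batches within a barn follow each other in time with a
#' one-week empty period.
#'
#' @param n_barns,n_batches layout (defaults 6 and 5).
#' @param first_start start of the first batch.
#' @param seed master seed; each batch gets a derived seed.
#' @param ... passed to [batch_config()] (e.g. `mode`, `corruption`).
#' @return list of `pig_batch` objects.
#' @export
simulate_farm <- function(n_barns = 6, n_batches = 5,
                          first_start = as.POSIXct("2020-12-01 00:00:00", tz = "UTC"),
                          seed = 1, ...) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_barns * n_batches),
                  n_barns, n_batches)
  out <- list()
  for (b in seq_len(n_barns)) {
    for (k in seq_len(n_batches)) {
      start <- first_start + (k - 1) * (16 * 7 * 24 * 3600)  # 15 wk + 1 wk empty
      cfg <- batch_config(start = start,
                          barn_id = sprintf("barn%02d", b),
                          batch_id = as.character(k),
                          seed = seeds[b, k], ...)
      out[[sprintf("barn%02d_batch%d", b, k)]] <- simulate_batch(cfg)
    }
  }
  out
}
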