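# Independent oracles and small fixture builders shared across tests.

# Dense multivariate-normal log-likelihood of a zero-mean ARMA sample, built
# from the ARMA autocovariance function (stats::ARMAacf / ARMAtoMA), entirely
# independent of the package's state-space filter.  `obs` optionally selects
# the observed subvector (marginal likelihood with missing entries dropped).
dense_arma_loglik <- function(phi, theta, sigma2, z, obs = seq_along(z)) {
  n <- length(z)
  if (!length(phi) && !length(theta)) {
    G <- diag(sigma2, n)[obs, obs, drop = FALSE]
  } else {
    psi <- c(1, stats::ARMAtoMA(ar = phi, ma = theta, lag.max = 5000))
    g0 <- sigma2 * sum(psi^2)
    rho <- stats::ARMAacf(ar = phi, ma = theta, lag.max = n - 1)
    G <- (g0 * stats::toeplitz(rho))[obs, obs, drop = FALSE]
  }
  z <- z[obs]
  L <- chol(G)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(L))) +
            sum(backsolve(L, z, transpose = TRUE)^2))
}

# random stationary/invertible subset specification + parameters (rejection
# sampling on the root check), for oracle-equivalence sweeps
random_subset_model <- function(max_p = 3, max_q = 3, margin = 1.05) {
  repeat {
    p <- sample(0:max_p, 1)
    q <- sample(0:max_q, 1)
    ar_lags <- if (p > 0) sort(sample(seq_len(p), sample(seq_len(p), 1))) else integer()
    ma_lags <- if (q > 0) sort(sample(seq_len(q), sample(seq_len(q), 1))) else integer()
    p <- if (length(ar_lags)) max(ar_lags) else 0
    q <- if (length(ma_lags)) max(ma_lags) else 0
    phi <- stats::setNames(runif(length(ar_lags), -0.7, 0.7), ar_lags)
    theta <- stats::setNames(runif(length(ma_lags), -0.7, 0.7), ma_lags)
    spec <- armax_spec(p, q, ar_lags, ma_lags)
    pars <- armax_params(mu = runif(1, -2, 2), phi = phi, theta = theta,
                         sigma2 = runif(1, 0.5, 2))
    d <- pigwater:::params_dense(pars, spec)
    if (pigwater:::min_root_modulus(d$phi, d$theta) > margin)
      return(list(spec = spec, params = pars))
  }
}

# hourly design matrix matching the shipped model's regressors
truth_design <- function(n, env_seed = 1) {
  env <- simulate_environment(n, cfg = environment_config(), seed = env_seed)
  hod <- as.integer(format(env$timestamp, "%H"))
  fday <- 1 + (seq_len(n) - 1) %/% 24
  cbind(harmonic_design(hod, 4),
        T = env$temperature, NH3 = env$nh3, N = as.numeric(fday))
}

# minimal fitted-model stub for functions that only read coefficients/se or
# the filter state
fake_fit <- function(coefficients, se = NULL, spec = NULL, estimates = NULL,
                     filter_state = NULL) {
  structure(list(coefficients = coefficients, se = se, spec = spec,
                 estimates = estimates, filter_state = filter_state),
            class = "armax_fit")
}

# drinking-only readings frame at exact 20-min cadence, constant volume
flat_readings <- function(n_hours, vol_per_reading = 1, pigs = 690,
                          barn = "b1", batch = "1",
                          start = as.POSIXct("2021-03-01 00:00:00", tz = "UTC")) {
  ts <- rep(start + 3600 * (seq_len(n_hours) - 1), each = 3) +
    rep(c(0, 1200, 2400), times = n_hours)
  data.frame(timestamp = ts, barn_id = barn, batch_id = batch,
             usage = "drinking", volume_L = vol_per_reading, pig_count = pigs)
}
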