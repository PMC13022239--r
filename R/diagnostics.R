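# Residual adequacy checks and descriptive analyses: Ljung-Box, Shapiro-Wilk,
# hourly consumption profiles with a hot/cold seasonal split, hour-of-day
# ANOVA, and harmonic-curve overlays.

#' Ljung-Box portmanteau test for residual autocorrelation
#'
#' Q = n(n+2) sum_k rho_k^2 / (n - k) over lags 1..`lags`, referred to a
#' chi-square distribution.  Degrees of freedom default to the number of lags
#' (so lag-24 diagnostics carry 24 df); `fitdf` subtracts the number of fitted
#' ARMA parameters for the conventional correction.
#'
#' @param residuals numeric series (NAs dropped).
#' @param lags number of autocorrelations pooled (default 24).
#' @param fitdf fitted-parameter correction subtracted from the df (default 0).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
ljung_box <- function(residuals, lags = 24, fitdf = 0) {
  x <- residuals[!is.na(residuals)]
  n <- length(x)
  if (n <= lags) stop("residual length must exceed the number of lags")
  cg <- correlogram(x, lags)   # errors on constant input
  rho <- cg$acf[-1]
  Q <- n * (n + 2) * sum(rho^2 / (n - seq_len(lags)))
  df <- lags - fitdf
  if (df < 1) stop("fitdf leaves no degrees of freedom")
  list(statistic = Q, df = df, p_value = pchisq(Q, df, lower.tail = FALSE))
}

#' Shapiro-Wilk normality test with large-sample subsampling
#'
#' Wraps [stats::shapiro.test()]; series longer than `max_n` (the statistic's
#' customary validity bound, default 5000) are reduced to a seeded random
#' subsample, whose size is reported.
#'
#' @param residuals numeric series (NAs dropped), >= 3 values.
#' @param max_n largest sample passed to the test.
#' @param seed seed for the subsample draw.
#' @return list with `W`, `p_value`, `n_used`.
#' @export
shapiro_wilk <- function(residuals, max_n = 5000, seed = 1) {
  x <- residuals[!is.na(residuals)]
  if (length(x) < 3) stop("need at least 3 non-missing residuals")
  if (length(x) > max_n) {
    set.seed(seed)
    x <- sample(x, max_n)
  }
  sw <- shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value, n_used = length(x))
}

#' Per-hour consumption profile, optionally split by season
#'
#' Mean, SD and count of consumption for each hour of day 0-23.  The seasonal
#' split follows the hot/cold calendar convention: hot = May-October, cold =
#' November-April, inclusive.
#'
#' @param series an hourly series data frame with `timestamp` (POSIXct) and
#'   `consumption` columns; missing consumption values are excluded.
#' @param season `"all"`, `"hot"` or `"cold"`.
#' @return data frame with `hour`, `mean`, `sd`, `n` (24 rows) and a `season`
#'   attribute.
#' @export
hourly_profile <- function(series, season = c("all", "hot", "cold")) {
  season <- match.arg(season)
  stopifnot(all(c("timestamp", "consumption") %in% names(series)))
  mo <- as.integer(format(series$timestamp, "%m"))
  keep <- switch(season,
                 all = rep(TRUE, nrow(series)),
                 hot = mo >= 5 & mo <= 10,
                 cold = mo >= 11 | mo <= 4)
  keep <- keep & !is.na(series$consumption)
  if (!any(keep)) stop("no observations after the season filter")
  hr <- as.integer(format(series$timestamp[keep], "%H"))
  x <- series$consumption[keep]
  out <- data.frame(hour = 0:23,
                    mean = NA_real_, sd = NA_real_, n = 0L)
  agg_mean <- tapply(x, hr, mean)
  agg_sd <- tapply(x, hr, sd)
  agg_n <- tapply(x, hr, length)
  idx <- as.integer(names(agg_mean)) + 1L
  out$mean[idx] <- agg_mean
  out$sd[idx] <- agg_sd
  out$n[idx] <- agg_n
  attr(out, "season") <- season
  out
}

#' One-way ANOVA of consumption on hour of day
#'
#' Fixed-effects one-way ANOVA testing whether mean consumption differs across
#' the 24 hours of the day (df1 = 23 when all hours are present).
#'
#' @inheritParams hourly_profile
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
hour_anova <- function(series) {
  stopifnot(all(c("timestamp", "consumption") %in% names(series)))
  ok <- !is.na(series$consumption)
  hr <- factor(as.integer(format(series$timestamp[ok], "%H")), levels = 0:23)
  hr <- droplevels(hr)
  x <- series$consumption[ok]
  if (nlevels(hr) < 2 || min(table(hr)) < 2)
    stop("need at least two hours with at least two observations each")
  a <- stats::anova(lm(x ~ hr))
  list(F = a[["F value"]][1], df1 = a[["Df"]][1], df2 = a[["Df"]][2],
       p_value = a[["Pr(>F)"]][1])
}

#' Harmonic components of the daily cycle
#'
#' Evaluates each sine/cosine harmonic wave and their sum on a 24-h grid, for
#' overlaying on an hourly profile.  Coefficients are named S1..Sk / C1..Ck as
#' in the model's design matrix.
#'
#' @param coefficients named numeric vector (subset of S1..S4, C1..C4).
#' @param hours evaluation grid (default 0:23).
#' @param base_period cycle length in hours (default 24).
#' @return data frame: `hour`, one column per harmonic (`H1`..`Hk`), `total`.
#' @export
harmonic_overlay <- function(coefficients, hours = 0:23, base_period = 24) {
  ks <- sort(unique(as.integer(gsub("[SC]", "", names(coefficients)))))
  if (!length(ks)) ks <- integer(0)
  out <- data.frame(hour = hours)
  total <- rep(0, length(hours))
  for (k in ks) {
    w <- 2 * pi * k * hours / base_period
    s <- coefficients[paste0("S", k)]
    cc <- coefficients[paste0("C", k)]
    wave <- (if (!is.na(s)) s * sin(w) else 0) +
      (if (!is.na(cc)) cc * cos(w) else 0)
    out[[paste0("H", k)]] <- wave
    total <- total + wave
  }
  out$total <- total
  out
}
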