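# h-step prediction from the end-of-sample filtered state, Gaussian intervals,
# standardized forecast errors and RMSE scoring.

#' h-step-ahead forecasts with prediction intervals
#'
#' Runs the state-space prediction recursion from the end-of-sample filtered
#' state of a fitted model.  Point forecasts are the regression mean plus the
#' predicted ARMA-error mean; intervals are Gaussian,
#' point +/- z * forecast SE, ignoring parameter-estimation uncertainty (the
#' standard ARIMA forecasting convention).
#'
#' @param fitted an `armax_fit`.
#' @param h forecast horizon (hours), >= 1.
#' @param X_future design matrix with `h` rows covering all model regressors
#'   (required when the model has regressors; future covariates are assumed
#'   known).
#' @param level interval coverage (default 0.95).
#' @return object of class `armax_forecast`: a data frame with columns
#'   `step`, `forecast`, `se`, `lower`, `upper`.
#' @export
forecast_h <- function(fitted, h, X_future = NULL, level = 0.95) {
  stopifnot(inherits(fitted, "armax_fit"))
  if (!is.numeric(h) || h < 1) stop("h must be a positive integer")
  h <- as.integer(h)
  sp <- fitted$spec
  if (length(sp$regressors)) {
    if (is.null(X_future)) stop("future covariates required for regressors: ",
                                paste(sp$regressors, collapse = ", "))
    missing_cols <- setdiff(sp$regressors, colnames(X_future))
    if (length(missing_cols))
      stop("X_future lacks regressor(s): ", paste(missing_cols, collapse = ", "))
    if (nrow(X_future) != h) stop("X_future must have h rows")
    if (anyNA(X_future[, sp$regressors]))
      stop("missing values in future covariates")
  }
  d <- params_dense(fitted$estimates, sp)
  pr <- ss_predict_cpp(fitted$filter_state$a, fitted$filter_state$P,
                       d$phi, d$theta, h)
  mean_path <- regression_mean(fitted$estimates, sp, X_future, h) + pr$mean
  se <- sqrt(fitted$estimates$sigma2 * pr$var)
  zq <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(step = seq_len(h), forecast = mean_path, se = se,
                    lower = mean_path - zq * se, upper = mean_path + zq * se)
  attr(out, "level") <- level
  class(out) <- c("armax_forecast", "data.frame")
  out
}

#' One-step-ahead predictions of a series under fixed parameters
#'
#' Runs the innovations filter over a (possibly new) series with the supplied
#' parameters and returns the rolling one-step predictions, their standard
#' errors and Gaussian intervals, with the realized values attached.  On the
#' training data the prediction errors are exactly the model's innovations.
#'
#' @inheritParams exact_loglik
#' @param level interval coverage (default 0.95).
#' @return an `armax_forecast` data frame with columns `step`, `forecast`,
#'   `se`, `lower`, `upper`, `actual`, `std_error` (NA at missing hours).
#' @export
one_step_forecasts <- function(spec, params, y, X = NULL, level = 0.95) {
  ll <- exact_loglik(spec, params, y, X)
  v <- attr(ll, "innovations")
  s2 <- attr(ll, "innovation_var")
  se <- sqrt(s2)
  pred <- y - v
  zq <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(step = seq_along(y), forecast = pred, se = se,
                    lower = pred - zq * se, upper = pred + zq * se,
                    actual = y, std_error = v / se)
  attr(out, "level") <- level
  class(out) <- c("armax_forecast", "data.frame")
  out
}

#' Standardized forecast errors
#'
#' (actual - forecast) / forecast SE, step by step.  Under a correctly
#' specified model these have mean ~ 0 and SD ~ 1.
#'
#' @param result an `armax_forecast`.
#' @param actual realized series aligned with the forecast horizon.
#' @return numeric vector.
#' @export
standardized_errors <- function(result, actual) {
  stopifnot(inherits(result, "armax_forecast"))
  if (length(actual) != nrow(result)) stop("actual must align with the horizon")
  if (any(result$se <= 0, na.rm = TRUE)) stop("zero forecast standard error")
  (actual - result$forecast) / result$se
}

#' Root mean squared error over non-missing pairs
#'
#' @param predicted,actual equal-length numeric vectors.
#' @return scalar RMSE.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("lengths differ")
  ok <- !is.na(predicted) & !is.na(actual)
  if (!any(ok)) stop("no overlapping non-missing pairs")
  sqrt(mean((predicted[ok] - actual[ok])^2))
}
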