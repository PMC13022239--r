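#' Subset ARMAX model specification
#'
#' Describes the structure of a regression-with-ARMA-errors model: the maximum
#' AR and MA orders `p` and `q`, the subsets of lags that carry free
#' coefficients (all other lags are fixed to zero), the names of the exogenous
#' regressors, and whether an intercept is estimated.  The errors follow a
#' subset ARMA(p, q) process; regressors enter the mean contemporaneously.
#'
#' @param p maximum autoregressive lag (>= 0).
#' @param q maximum moving-average lag (>= 0).
#' @param ar_lags integer vector of active AR lags, a subset of `1:p`.
#' @param ma_lags integer vector of active MA lags, a subset of `1:q`.
#' @param regressors character vector of design-matrix column names entering
#'   the regression mean.
#' @param intercept logical; estimate an intercept term.
#' @return an object of class `armax_spec`.
#' @examples
#' # the barn water-consumption model: subset ARMA(24, 24) with lags
#' # {1, 2, 22, 23, 24} on both sides plus harmonic/environment regressors
#' armax_spec(24, 24, ar_lags = c(1, 2, 22, 23, 24),
#'            ma_lags = c(1, 2, 22, 23, 24),
#'            regressors = c("S1", "C1", "T", "NH3", "N"))
#' @export
armax_spec <- function(p, q, ar_lags = seq_len(p), ma_lags = seq_len(q),
                       regressors = character(), intercept = TRUE) {
  stopifnot(length(p) == 1, length(q) == 1, p >= 0, q >= 0)
  ar_lags <- sort(unique(as.integer(ar_lags)))
  ma_lags <- sort(unique(as.integer(ma_lags)))
  if (length(ar_lags) && (min(ar_lags) < 1 || max(ar_lags) > p))
    stop("ar_lags must lie in 1..p")
  if (length(ma_lags) && (min(ma_lags) < 1 || max(ma_lags) > q))
    stop("ma_lags must lie in 1..q")
  structure(list(p = as.integer(p), q = as.integer(q),
                 ar_lags = ar_lags, ma_lags = ma_lags,
                 regressors = as.character(regressors),
                 intercept = isTRUE(intercept)),
            class = "armax_spec")
}

#' @export
print.armax_spec <- function(x, ...) {
  cat(sprintf("Subset ARMAX(%d, %d) specification\n", x$p, x$q))
  cat("  active AR lags:", if (length(x$ar_lags)) paste(x$ar_lags, collapse = ", ") else "none", "\n")
  cat("  active MA lags:", if (length(x$ma_lags)) paste(x$ma_lags, collapse = ", ") else "none", "\n")
  cat("  regressors:", if (length(x$regressors)) paste(x$regressors, collapse = ", ") else "none", "\n")
  cat("  intercept:", x$intercept, "\n")
  invisible(x)
}

#' Number of free coefficients of a specification
#'
#' Counts intercept, regression coefficients and active ARMA lags; the
#' innovation variance is counted separately by [information_criteria()]
#' callers (the fitter uses `n_coef(spec) + 1`).
#' @param spec an `armax_spec`.
#' @return integer count.
#' @export
n_coef <- function(spec) {
  as.integer(spec$intercept) + length(spec$regressors) +
    length(spec$ar_lags) + length(spec$ma_lags)
}

#' Parameter set for a subset ARMAX model
#'
#' Holds the intercept `mu`, sparse AR and MA coefficient maps (named by lag),
#' regression coefficients `eta` (named by regressor), and the innovation
#' variance `sigma2`.
#'
#' @param mu intercept, in consumption units (mL/pig/h for the barn model).
#' @param phi named numeric vector of AR coefficients; names are lags.
#' @param theta named numeric vector of MA coefficients; names are lags.
#' @param eta named numeric vector of regression coefficients.
#' @param sigma2 innovation variance (> 0).
#' @return an object of class `armax_params`.
#' @export
armax_params <- function(mu = 0, phi = numeric(), theta = numeric(),
                         eta = numeric(), sigma2 = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1, sigma2 > 0)
  if (length(phi) && is.null(names(phi))) stop("phi must be named by lag")
  if (length(theta) && is.null(names(theta))) stop("theta must be named by lag")
  if (length(eta) && is.null(names(eta))) stop("eta must be named by regressor")
  structure(list(mu = mu, phi = phi, theta = theta, eta = eta,
                 sigma2 = sigma2),
            class = "armax_params")
}

#' @export
print.armax_params <- function(x, ...) {
  cat("ARMAX parameter set\n")
  cat("  mu =", format(x$mu), " sigma2 =", format(x$sigma2), "\n")
  if (length(x$phi)) cat("  phi:", paste0("[", names(x$phi), "] ", format(x$phi), collapse = "  "), "\n")
  if (length(x$theta)) cat("  theta:", paste0("[", names(x$theta), "] ", format(x$theta), collapse = "  "), "\n")
  if (length(x$eta)) cat("  eta:", paste0(names(x$eta), " = ", format(x$eta), collapse = "  "), "\n")
  invisible(x)
}

# dense lag-coefficient vectors (zeros at inactive lags)
full_lag_vector <- function(map, order) {
  out <- numeric(order)
  if (length(map)) out[as.integer(names(map))] <- map
  out
}

params_dense <- function(params, spec) {
  list(phi = full_lag_vector(params$phi, spec$p),
       theta = full_lag_vector(params$theta, spec$q))
}

#' Root moduli of AR / MA lag polynomials
#'
#' Computes the moduli of the roots of 1 - phi_1 z - ... - phi_p z^p (AR) or
#' 1 + theta_1 z + ... + theta_q z^q (MA).  Stationarity (AR) and
#' invertibility (MA) require all moduli strictly outside the unit circle.
#'
#' @param coefs dense coefficient vector (zeros allowed at inactive lags).
#' @param type `"ar"` or `"ma"`.
#' @return numeric vector of root moduli (possibly empty).
#' @export
arma_root_moduli <- function(coefs, type = c("ar", "ma")) {
  type <- match.arg(type)
  if (!length(coefs) || all(coefs == 0)) return(numeric())
  poly <- if (type == "ar") c(1, -coefs) else c(1, coefs)
  # trim trailing zero coefficients so polyroot sees the true degree
  deg <- max(which(poly != 0))
  if (deg == 1) return(numeric())
  Mod(polyroot(poly[seq_len(deg)]))
}

min_root_modulus <- function(phi_dense, theta_dense) {
  m <- c(arma_root_moduli(phi_dense, "ar"), arma_root_moduli(theta_dense, "ma"))
  if (!length(m)) Inf else min(m)
}

assert_stationary <- function(phi_dense, theta_dense, margin = 1.001) {
  mar <- arma_root_moduli(phi_dense, "ar")
  if (length(mar) && min(mar) <= margin)
    stop(sprintf("non-stationary AR polynomial: min root modulus %.5f <= %.3f",
                 min(mar), margin))
  mma <- arma_root_moduli(theta_dense, "ma")
  if (length(mma) && min(mma) <= margin)
    stop(sprintf("non-invertible MA polynomial: min root modulus %.5f <= %.3f",
                 min(mma), margin))
  invisible(TRUE)
}

#' The fitted barn water-consumption model shipped as generator ground truth
#'
#' Returns the subset ARMAX(24, 24) specification and coefficient set used as
#' the model-truth defaults of the synthetic generator: active AR and MA lags
#' \{1, 2, 22, 23, 24\}, four harmonic sine/cosine pairs of the 24-h cycle,
#' outside temperature, ammonia and fattening day as regressors, unit
#' innovation variance, zero intercept.
#'
#' @return a list with elements `spec` (an [armax_spec()]) and `params`
#'   (an [armax_params()]).
#' @export
barn_truth_model <- function() {
  lags <- c(1, 2, 22, 23, 24)
  spec <- armax_spec(24, 24, ar_lags = lags, ma_lags = lags,
                     regressors = c("S1", "S2", "S3", "S4",
                                    "C1", "C2", "C3", "C4",
                                    "T", "NH3", "N"),
                     intercept = TRUE)
  params <- armax_params(
    mu = 0,
    phi = c(`1` = 1.1045, `2` = -0.3326, `22` = -0.2183,
            `23` = 0.8993, `24` = -0.4818),
    theta = c(`1` = -0.6963, `2` = 0.1583, `22` = 0.2733,
              `23` = -0.7566, `24` = 0.2893),
    eta = c(S1 = -0.7513, S2 = -0.4167, S3 = 0.2275, S4 = 0.1351,
            C1 = -0.7394, C2 = -0.1976, C3 = 0.1960, C4 = 0.0482,
            T = 0.0198, NH3 = -0.0142, N = -0.1196),
    sigma2 = 1)
  list(spec = spec, params = params)
}
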