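# Deterministic regressor matrices: harmonic seasonal terms of the 24-h
# cycle, fattening-day trend and environmental covariates.

#' Harmonic design columns of the daily cycle
#'
#' Sine/cosine pairs at the first `n_harmonics` harmonics of the base period
#' (24, 12, 8 and 6 h for the default four): columns `S1..Sk` then `C1..Ck`,
#' with `Sk = sin(2 pi k h / P)` and `Ck = cos(2 pi k h / P)`.  Depends only
#' on hour of day (phase 0 at midnight).
#'
#' @param hour_of_day numeric vector of hours (0-23, or any hour index —
#'   equivalent modulo the base period for harmonics that divide it).
#' @param n_harmonics number of harmonic pairs (default 4).
#' @param base_period cycle length in hours (default 24).
#' @return numeric matrix with `2 * n_harmonics` named columns.
#' @export
harmonic_design <- function(hour_of_day, n_harmonics = 4, base_period = 24) {
  stopifnot(n_harmonics >= 1, base_period > 0)
  ks <- seq_len(n_harmonics)
  S <- vapply(ks, function(k) sin(2 * pi * k * hour_of_day / base_period),
              numeric(length(hour_of_day)))
  C <- vapply(ks, function(k) cos(2 * pi * k * hour_of_day / base_period),
              numeric(length(hour_of_day)))
  out <- cbind(matrix(S, nrow = length(hour_of_day)),
               matrix(C, nrow = length(hour_of_day)))
  colnames(out) <- c(paste0("S", ks), paste0("C", ks))
  out
}

#' Covariate design columns from an hourly series
#'
#' Returns the requested covariates in the requested order, mapping the
#' model's column names to series columns: `T` = temperature (degC), `NH3` =
#' ammonia (ppm), `N` = fattening day (integer days since batch start,
#' `1 + floor(hours/24)` — recomputed from timestamps when absent).  Rows
#' with missing covariate values keep their NA (they inherit the series
#' missing mask downstream).
#'
#' @param series hourly series data frame.
#' @param choices character vector of design names (subset of `T`, `NH3`, `N`).
#' @return numeric matrix with `length(choices)` columns, `nrow(series)` rows.
#' @export
covariate_design <- function(series, choices = c("T", "NH3", "N")) {
  map <- c(T = "temperature", NH3 = "nh3", N = "fattening_day")
  cols <- list()
  for (ch in choices) {
    src <- if (ch %in% names(map)) map[[ch]] else ch
    if (src %in% names(series)) {
      cols[[ch]] <- as.numeric(series[[src]])
    } else if (ch == "N") {
      h0 <- min(series$timestamp)
      cols[[ch]] <- 1 + floor(as.numeric(difftime(series$timestamp, h0,
                                                  units = "hours")) / 24)
    } else {
      stop("covariate not found on series: ", ch)
    }
  }
  out <- matrix(numeric(0), nrow = nrow(series), ncol = 0)
  if (length(cols)) {
    out <- do.call(cbind, cols)
    colnames(out) <- choices
  }
  out
}

#' Full default design matrix: harmonics, temperature, ammonia, trend
#'
#' Binds [harmonic_design()] (hour of day from the timestamps) and
#' [covariate_design()]; the default yields the 11 columns
#' S1..S4, C1..C4, T, NH3, N.
#'
#' @param series hourly series data frame with `timestamp`.
#' @param n_harmonics harmonic pairs (default 4).
#' @param covariates covariate names (default `c("T", "NH3", "N")`).
#' @return numeric matrix.
#' @export
build_design <- function(series, n_harmonics = 4,
                         covariates = c("T", "NH3", "N")) {
  hod <- as.integer(format(series$timestamp, "%H"))
  H <- harmonic_design(hod, n_harmonics)
  X <- covariate_design(series, covariates)
  out <- cbind(H, X)
  if (any(!is.finite(out[!is.na(out)])))
    stop("non-finite design entries")
  out
}
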