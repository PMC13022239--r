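# Cleaning rules for raw meter readings: usage-type filtering, hourly
# aggregation with missing-hour flagging, per-pig normalization (L -> mL),
# outlier/negative exclusion at 10 L/pig/h, train/test partitioning.
# Removed records become missing hours, preserving the hourly grid the
# state-space likelihood expects.

USAGE_LEVELS <- c("drinking", "cooling", "cleaning")
READINGS_PER_HOUR <- 3L
OUTLIER_THRESHOLD_ML <- 10000  # 10 L/pig/h

#' Keep drinking records only
#'
#' Removes cooling and cleaning usage records; unknown usage labels are an
#' error (the usage set is closed).
#'
#' @param readings raw-readings data frame with a `usage` column.
#' @return list with `readings` (drinking only), `removed`, `total`,
#'   `fraction`.
#' @export
filter_usage_type <- function(readings) {
  if (!"usage" %in% names(readings)) stop("usage column required")
  bad <- setdiff(unique(readings$usage), USAGE_LEVELS)
  if (length(bad)) stop("unknown usage type: ", paste(bad, collapse = ", "))
  keep <- readings$usage == "drinking"
  if (!any(keep)) warning("no drinking records after usage filtering")
  list(readings = readings[keep, , drop = FALSE],
       removed = sum(!keep), total = length(keep),
       fraction = mean(!keep))
}

#' Aggregate sub-hourly readings into clock-hour bins
#'
#' Sums reading volumes into left-closed local clock hours [h:00, h+1:00).
#' Hours with fewer than the expected number of sub-readings (20-min cadence:
#' 3/hour), and grid hours with no readings at all, are flagged missing.
#' Duplicate readings for the same interval are an error.
#'
#' @param readings drinking-only readings (`timestamp`, `barn_id`,
#'   `batch_id`, `volume_L`, `pig_count`).
#' @param expected_per_hour readings per hour implied by the cadence.
#' @return data frame: `timestamp` (hour), `barn_id`, `batch_id`,
#'   `volume_L`, `pig_count`, `n_readings`, `missing`.
#' @export
aggregate_hourly <- function(readings, expected_per_hour = READINGS_PER_HOUR) {
  stopifnot(all(c("timestamp", "barn_id", "batch_id", "volume_L") %in% names(readings)))
  key <- paste(readings$barn_id, readings$batch_id,
               format(readings$timestamp, "%Y-%m-%d %H:%M:%S"))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate reading for interval: ", dup)
  }
  out <- list()
  for (grp in split(readings,
                    paste(readings$barn_id, readings$batch_id, sep = "\r"))) {
    hour <- as.POSIXct(trunc(grp$timestamp, "hours"))
    agg_v <- tapply(grp$volume_L, format(hour, "%Y-%m-%d %H"), sum)
    agg_n <- tapply(grp$volume_L, format(hour, "%Y-%m-%d %H"), length)
    agg_p <- tapply(grp$pig_count, format(hour, "%Y-%m-%d %H"),
                    function(x) x[1])
    grid <- seq(min(hour), max(hour), by = 3600)
    gk <- format(grid, "%Y-%m-%d %H")
    v <- unname(agg_v[gk]); n <- unname(agg_n[gk]); p <- unname(agg_p[gk])
    n[is.na(n)] <- 0L
    miss <- n < expected_per_hour
    out[[length(out) + 1]] <- data.frame(
      timestamp = grid, barn_id = grp$barn_id[1], batch_id = grp$batch_id[1],
      volume_L = ifelse(miss, NA_real_, v),
      pig_count = p, n_readings = as.integer(n), missing = miss)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-pig normalization: barn litres per hour to mL/pig/h
#'
#' `1000 * total / pig_count`.  Records whose pig count is missing or
#' non-positive cannot be paired and yield `NA` (counted as unpaired by the
#' cleaning pipeline).
#'
#' @param total_volume_L hourly barn total (L/h).
#' @param pig_count pigs present that hour.
#' @return consumption in mL/pig/h (NA where unpaired).
#' @export
normalize_per_pig <- function(total_volume_L, pig_count) {
  out <- 1000 * total_volume_L / pig_count
  out[is.na(pig_count) | pig_count <= 0] <- NA_real_
  out
}

#' Exclude extreme and negative hourly values
#'
#' Marks consumption strictly above `threshold` (default 10,000 mL/pig/h =
#' 10 L/pig/h) or strictly below zero as missing; values exactly at the
#' threshold are retained.
#'
#' @param series hourly series data frame with `consumption` and `missing`.
#' @param threshold exclusion threshold in mL/pig/h (> 0).
#' @return list with `series` (values removed -> NA, missing flagged),
#'   `n_extreme`, `n_negative`.
#' @export
remove_outliers <- function(series, threshold = OUTLIER_THRESHOLD_ML) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be positive")
  x <- series$consumption
  extreme <- !is.na(x) & x > threshold
  negative <- !is.na(x) & x < 0
  series$consumption[extreme | negative] <- NA_real_
  series$missing <- series$missing | extreme | negative
  list(series = series, n_extreme = sum(extreme), n_negative = sum(negative))
}

#' Clean raw meter readings into an analysis-ready per-pig hourly series
#'
#' Applies the full cleaning chain: usage filtering, hourly aggregation with
#' missing-hour flagging, per-pig normalization to mL/pig/h, unpaired-record
#' removal, and the 10 L/pig/h and negative-value exclusions.  Covariates are
#' joined by hour when supplied.  Every removed record becomes a missing hour,
#' so the hourly grid is preserved.
#'
#' @param readings raw readings (any usage mix).
#' @param covariates optional hourly table with `timestamp`, `temperature`,
#'   `nh3` to join.
#' @param threshold outlier threshold in mL/pig/h.
#' @return list with `series` (hourly data frame: `timestamp`, `barn_id`,
#'   `batch_id`, `consumption`, `pig_count`, covariates, `fattening_day`,
#'   `missing`) and `report` (a `cleaning_report`).
#' @export
clean_series <- function(readings, covariates = NULL,
                         threshold = OUTLIER_THRESHOLD_ML) {
  fu <- filter_usage_type(readings)
  hourly <- aggregate_hourly(fu$readings)
  n_missing_hours <- sum(hourly$missing)
  consumption <- normalize_per_pig(hourly$volume_L, hourly$pig_count)
  unpaired <- !hourly$missing & is.na(consumption) & !is.na(hourly$volume_L)
  series <- data.frame(timestamp = hourly$timestamp,
                       barn_id = hourly$barn_id, batch_id = hourly$batch_id,
                       consumption = consumption,
                       pig_count = hourly$pig_count,
                       missing = hourly$missing | unpaired)
  series$consumption[series$missing] <- NA_real_
  ro <- remove_outliers(series, threshold)
  series <- ro$series
  if (!is.null(covariates)) {
    i <- match(format(series$timestamp, "%Y-%m-%d %H"),
               format(covariates$timestamp, "%Y-%m-%d %H"))
    series$temperature <- covariates$temperature[i]
    series$nh3 <- covariates$nh3[i]
  }
  # fattening day from hours since batch start, per barn x batch
  series$fattening_day <- NA_integer_
  for (g in split(seq_len(nrow(series)),
                  paste(series$barn_id, series$batch_id, sep = "\r"))) {
    h0 <- min(series$timestamp[g])
    series$fattening_day[g] <-
      1L + as.integer(floor(as.numeric(difftime(series$timestamp[g], h0,
                                                units = "hours")) / 24))
  }
  n_hours <- nrow(series)
  report <- data.frame(
    rule = c("usage_type", "missing_hours", "unpaired", "negative", "extreme"),
    removed = c(fu$removed, n_missing_hours, sum(unpaired),
                ro$n_negative, ro$n_extreme),
    total = c(fu$total, rep(n_hours, 4)),
    stringsAsFactors = FALSE)
  report$fraction <- report$removed / report$total
  attr(report, "retained") <- sum(!series$missing)
  class(report) <- c("cleaning_report", "data.frame")
  list(series = series, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("retained hourly records:", attr(x, "retained"), "\n")
  invisible(x)
}

#' Train/test partition of a set of series
#'
#' Default policy holds out the last batch (latest start) of every barn as the
#' test set, mirroring a one-batch-per-barn holdout; `"all-train"` keeps
#' everything for estimation.
#'
#' @param series_set list of hourly series data frames, each a single
#'   barn x batch.
#' @param policy `"last-batch"` or `"all-train"`.
#' @return list with `train` and `test` (disjoint sublists) and
#'   `composition` (data frame of assignments).
#' @export
split_train_test <- function(series_set, policy = c("last-batch", "all-train")) {
  policy <- match.arg(policy)
  info <- do.call(rbind, lapply(seq_along(series_set), function(i) {
    s <- series_set[[i]]
    data.frame(index = i, barn_id = s$barn_id[1], batch_id = s$batch_id[1],
               start = min(s$timestamp))
  }))
  if (policy == "all-train") {
    info$set <- "train"
    return(list(train = series_set, test = list(), composition = info))
  }
  counts <- table(info$barn_id)
  if (any(counts < 2))
    stop("barn(s) with a single batch under the last-batch policy: ",
         paste(names(counts)[counts < 2], collapse = ", "),
         "; use policy = \"all-train\"")
  info$set <- "train"
  for (b in unique(info$barn_id)) {
    rows <- which(info$barn_id == b)
    info$set[rows[which.max(as.numeric(info$start[rows]))]] <- "test"
  }
  list(train = series_set[info$index[info$set == "train"]],
       test = series_set[info$index[info$set == "test"]],
       composition = info)
}
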