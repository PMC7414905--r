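#' Diel summary of a ground-temperature sensor log
#'
#' Splits a fixed-interval temperature record into day (default 7:00-18:00,
#' half-open) and night samples by local clock time and reports the mean,
#' maximum and minimum of each partition plus the thermal amplitude, defined
#' as the maximum day temperature minus the minimum night temperature. By
#' default the amplitude uses the record-wide extremes (`amplitude =
#' "global"`); `"daily"` instead averages the per-calendar-day day-maximum
#' minus night-minimum.
#'
#' @param log Data frame with columns `timestamp` (`POSIXct` or parseable
#'   strings) and `temp_c`.
#' @param day_start,day_end Daytime window bounds in hours.
#' @param amplitude `"global"` (default) or `"daily"`.
#' @return A list of class `diel_summary`: `day_mean`, `day_max`, `day_min`,
#'   `night_mean`, `night_max`, `night_min`, `amplitude`, `n_days`.
#' @export
summarize_sensor_log <- function(log, day_start = 7, day_end = 18,
                                 amplitude = c("global", "daily")) {
  amplitude <- match.arg(amplitude)
  stopifnot(all(c("timestamp", "temp_c") %in% names(log)))
  ts <- as.POSIXct(log$timestamp, tz = "UTC")
  lt <- as.POSIXlt(ts)
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  is_day <- h >= day_start & h < day_end
  if (!any(is_day) || all(is_day)) {
    stop("log must contain both day and night samples")
  }
  v <- log$temp_c
  date <- as.Date(ts)
  amp <- if (amplitude == "global") {
    max(v[is_day]) - min(v[!is_day])
  } else {
    dmax <- tapply(v[is_day], date[is_day], max)
    nmin <- tapply(v[!is_day], date[!is_day], min)
    common <- intersect(names(dmax), names(nmin))
    mean(dmax[common] - nmin[common])
  }
  res <- list(day_mean = mean(v[is_day]), day_max = max(v[is_day]),
              day_min = min(v[is_day]), night_mean = mean(v[!is_day]),
              night_max = max(v[!is_day]), night_min = min(v[!is_day]),
              amplitude = amp, n_days = length(unique(date)))
  class(res) <- "diel_summary"
  res
}

#' @method print diel_summary
#' @export
print.diel_summary <- function(x, ...) {
  cat(sprintf("<diel_summary> %d days\n", x$n_days))
  cat(sprintf("  day:   mean %.2f, max %.2f, min %.2f degC\n",
              x$day_mean, x$day_max, x$day_min))
  cat(sprintf("  night: mean %.2f, max %.2f, min %.2f degC\n",
              x$night_mean, x$night_max, x$night_min))
  cat(sprintf("  thermal amplitude: %.2f degC\n", x$amplitude))
  invisible(x)
}

#' @describeIn summarize_sensor_log one-row data frame version (handy for
#'   binding across sites).
#' @param x A `diel_summary`.
#' @param ... Unused.
#' @export
as.data.frame.diel_summary <- function(x, ...) {
  data.frame(day_mean = x$day_mean, day_max = x$day_max, day_min = x$day_min,
             night_mean = x$night_mean, night_max = x$night_max,
             night_min = x$night_min, amplitude = x$amplitude,
             n_days = x$n_days)
}
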