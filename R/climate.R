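# Daily meteorology -> heat-, water- and cold-related climate indices.
# Windows follow the dendroclimatological convention used throughout the
# package: vegetation period (VP) = current April-September; previous
# winter (PW) = previous October-current March.

MONTH_LABELS <- toupper(month.abb)

#' Calendar windows for climate aggregation
#'
#' @param year Calendar year the window is attributed to.
#' @param month Month number (1-12), for `month_window()`.
#' @return A list with `start` and `end` dates (inclusive).
#' @export
month_window <- function(year, month) {
  start <- as.Date(sprintf("%04d-%02d-01", year, month))
  list(start = start, end = seq(start, by = "1 month", length.out = 2)[2] - 1)
}

#' @rdname month_window
#' @export
vegetation_period <- function(year) {
  list(
    start = as.Date(sprintf("%04d-04-01", year)),
    end = as.Date(sprintf("%04d-09-30", year))
  )
}

#' @rdname month_window
#' @export
previous_winter <- function(year) {
  list(
    start = as.Date(sprintf("%04d-10-01", year - 1)),
    end = as.Date(sprintf("%04d-03-31", year))
  )
}

#' Aggregate a daily variable over a calendar window
#'
#' Arithmetic mean (temperatures, VPD) or sum (precipitation, PET, heat
#' sum) of a daily variable over all days of the window. Aborts when more
#' than `max_missing` of the window's days are absent or `NA`.
#'
#' @param daily Daily climate table with a `date` column.
#' @param window A window as returned by [month_window()],
#'   [vegetation_period()] or [previous_winter()].
#' @param var Name of the column to aggregate.
#' @param statistic `"mean"` or `"sum"`.
#' @param max_missing Tolerated missing fraction of window days
#'   (default 0.05).
#' @return A scalar.
#' @export
aggregate_period <- function(daily, window, var, statistic = c("mean", "sum"),
                             max_missing = 0.05) {
  statistic <- match.arg(statistic)
  days <- seq(window$start, window$end, by = "1 day")
  sel <- daily[daily$date >= window$start & daily$date <= window$end, ]
  v <- sel[[var]][match(days, sel$date)]
  n_missing <- sum(is.na(v))
  if (n_missing > max_missing * length(days)) {
    abort(sprintf(
      "Window %s..%s: %d of %d days missing for `%s` (tolerance %.0f%%).",
      window$start, window$end, n_missing, length(days), var,
      100 * max_missing
    ))
  }
  v <- v[!is.na(v)]
  if (statistic == "mean") mean(v) else sum(v)
}

#' Heat sum above 20 degrees C
#'
#' Sum of the positive exceedances of daily mean temperature above 20 C
#' over the window (strict inequality: a 20.0 C day contributes zero).
#'
#' @inheritParams aggregate_period
#' @return Degree-days (C d).
#' @export
heat_sum <- function(daily, window, max_missing = 0.05) {
  d2 <- daily %>% mutate(hs_excess = pmax(.data$tmean - 20, 0))
  aggregate_period(d2, window, "hs_excess", "sum", max_missing)
}

#' Threshold day counts: hot, frost, ice and rain days
#'
#' Counts days in the window with, respectively, Tmax >= 30 C (hot),
#' Tmin <= 0 C (frost), Tmax <= 0 C (ice), precipitation > 1.0 mm (rain;
#' note the strict inequality, unlike the inclusive temperature
#' thresholds).
#'
#' @inheritParams aggregate_period
#' @param kind One of `"hot"`, `"frost"`, `"ice"`, `"rain"`.
#' @return An integer count.
#' @export
threshold_day_count <- function(daily, window,
                                kind = c("hot", "frost", "ice", "rain"),
                                max_missing = 0.05) {
  kind <- match.arg(kind)
  d2 <- switch(kind,
    hot = mutate(daily, flag = as.numeric(.data$tmax >= 30)),
    frost = mutate(daily, flag = as.numeric(.data$tmin <= 0)),
    ice = mutate(daily, flag = as.numeric(.data$tmax <= 0)),
    rain = mutate(daily, flag = as.numeric(.data$ppt > 1.0))
  )
  aggregate_period(d2, window, "flag", "sum", max_missing)
}

#' Vapour pressure deficit
#'
#' Difference between saturation and actual vapour pressure,
#' \eqn{VPD = e_s(T) (1 - rh/100)}, with the Magnus-type saturation
#' formula \eqn{e_s(T) = 6.1078 \exp(17.27 T / (T + 237.3))} hPa. Monthly
#' and seasonal VPD values are arithmetic means of *daily maximum* VPD;
#' with 10-min data the daily maximum is taken over the sub-daily samples,
#' otherwise it is approximated from daily Tmax and daily mean relative
#' humidity.
#'
#' @param t Air temperature, degrees C.
#' @param rh Relative humidity, percent in \[0, 100\].
#' @return VPD in hPa (non-negative).
#' @examples
#' vpd(20, 50) # about 11.7 hPa
#' @export
vpd <- function(t, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    abort("`rh` must lie in [0, 100] %.")
  }
  es <- saturation_vp(t)
  pmax(es - (rh / 100) * es, 0)
}

#' @rdname vpd
#' @export
saturation_vp <- function(t) {
  6.1078 * exp(17.27 * t / (t + 237.3))
}

#' @rdname vpd
#' @param subdaily A table with columns `datetime` (POSIXct or Date-time),
#'   `temp`, `rh`: sub-daily (e.g. 10-min) samples.
#' @return `daily_max_vpd()`: a tibble `date`, `vpd_max`.
#' @export
daily_max_vpd <- function(subdaily) {
  subdaily %>%
    mutate(date = as.Date(.data$datetime)) %>%
    group_by(.data$date) %>%
    summarise(vpd_max = max(vpd(.data$temp, .data$rh)), .groups = "drop")
}

#' @rdname vpd
#' @inheritParams aggregate_period
#' @param daily Daily table; must carry either a precomputed `vpd_max`
#'   column (from [daily_max_vpd()]) or `tmax` and `rh` for the fallback.
#' @export
mean_daily_max_vpd <- function(daily, window, max_missing = 0.05) {
  if (!"vpd_max" %in% names(daily)) {
    daily <- mutate(daily, vpd_max = vpd(.data$tmax, .data$rh))
  }
  aggregate_period(daily, window, "vpd_max", "mean", max_missing)
}
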