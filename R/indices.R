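# The per-year climate index table: every heat-, water- and cold-related
# variable at the window(s) it is defined for (monthly, vegetation period,
# previous winter), plus spei3. This is the table both the stress-year
# screen and the correlation functions consume.

# (variable, window-kind) pairs that are defined for analysis.
INDEX_WINDOWS <- list(
  tmean = c("month", "VP", "PW"),
  hs    = c("month", "VP"),
  nhd   = c("month", "VP"),
  vpd   = c("month", "VP"),
  ppt   = c("month", "VP", "PW"),
  nrd   = c("month", "VP", "PW"),
  spei3 = c("month", "VP"),
  nfd   = c("month", "VP", "PW"),
  nid   = c("month", "PW")
)

#' Build the climate index table from daily records
#'
#' Computes, per year, the nine analysis variables: mean temperature
#' (`tmean`, C), heat sum above 20 C (`hs`, C d), number of hot days
#' (`nhd`, Tmax >= 30 C), mean daily-maximum vapour pressure deficit
#' (`vpd`, hPa), precipitation sum (`ppt`, mm), number of rain days
#' (`nrd`, PPT > 1 mm), 3-month SPEI (`spei3`), number of frost days
#' (`nfd`, Tmin <= 0 C) and number of ice days (`nid`, Tmax <= 0 C) —
#' each over the windows it is defined for: calendar months, the
#' vegetation period (VP, April-September) and/or the previous winter
#' (PW, previous October-current March). Windows with day coverage below
#' `1 - max_missing` yield `NA`.
#'
#' @param daily Daily climate table: `date`, `tmin`, `tmax`, `tmean`,
#'   `ppt`, optionally `rh` (needed for VPD), `pet` (otherwise Thornthwaite
#'   PET from `latitude` feeds SPEI) and `vpd_max` (from [daily_max_vpd()]
#'   on sub-daily data; otherwise approximated from `tmax` and `rh`).
#' @param latitude Site latitude (decimal degrees) for Thornthwaite PET
#'   when no `pet` column is present.
#' @param spei_scale SPEI aggregation scale in months (default 3).
#' @param spei_calibration Calibration years for SPEI (default: all).
#' @param max_missing Tolerated missing-day fraction per window.
#' @return A tibble `year`, `variable`, `window`, `value`; `window` is
#'   `"JAN"`..`"DEC"`, `"VP"` or `"PW"`.
#' @export
climate_indices <- function(daily, latitude = 49.93, spei_scale = 3L,
                            spei_calibration = NULL, max_missing = 0.05) {
  daily <- as_tibble(daily) %>% arrange(.data$date)
  if (anyDuplicated(daily$date)) abort("Duplicate dates in `daily`.")
  has_rh <- "rh" %in% names(daily)
  if (!"vpd_max" %in% names(daily) && has_rh) {
    daily <- mutate(daily, vpd_max = vpd(.data$tmax, .data$rh))
  }
  daily <- daily %>%
    mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m")),
      hs_x = pmax(.data$tmean - 20, 0),
      hot = as.numeric(.data$tmax >= 30),
      frost = as.numeric(.data$tmin <= 0),
      ice = as.numeric(.data$tmax <= 0),
      rain = as.numeric(.data$ppt > 1.0)
    )

  summarise_block <- function(d) {
    summarise(d,
      n_days = dplyr::n(),
      tmean = mean(.data$tmean),
      ppt = sum(.data$ppt),
      hs = sum(.data$hs_x),
      nhd = sum(.data$hot),
      nfd = sum(.data$frost),
      nid = sum(.data$ice),
      nrd = sum(.data$rain),
      vpd = if ("vpd_max" %in% names(daily)) mean(.data$vpd_max) else NA_real_,
      .groups = "drop"
    )
  }

  mon <- daily %>%
    group_by(.data$year, .data$month) %>%
    summarise_block() %>%
    mutate(
      expected = days_in_month(.data$year, .data$month),
      window = MONTH_LABELS[.data$month]
    )

  vp <- daily %>%
    filter(.data$month %in% 4:9) %>%
    group_by(.data$year) %>%
    summarise_block() %>%
    mutate(
      expected = vapply(
        .data$year,
        function(y) window_length(vegetation_period(y)), numeric(1)
      ),
      window = "VP"
    )

  pw <- daily %>%
    mutate(year = ifelse(.data$month >= 10L, .data$year + 1L, .data$year)) %>%
    filter(.data$month %in% c(10:12, 1:3)) %>%
    group_by(.data$year) %>%
    summarise_block() %>%
    mutate(
      expected = vapply(
        .data$year,
        function(y) window_length(previous_winter(y)), numeric(1)
      ),
      window = "PW"
    )

  blocks <- bind_rows(mon, vp, pw) %>%
    mutate(covered = .data$n_days >= (1 - max_missing) * .data$expected)

  long <- blocks %>%
    select(-"month") %>%
    tidyr::pivot_longer(
      cols = c("tmean", "ppt", "hs", "nhd", "nfd", "nid", "nrd", "vpd"),
      names_to = "variable", values_to = "value"
    ) %>%
    mutate(value = ifelse(.data$covered, .data$value, NA_real_)) %>%
    select("year", "variable", "window", "value")

  # spei3 from the monthly water balance
  monthly <- monthly_climate(daily)
  if (!"pet" %in% names(monthly)) {
    full_years <- names(which(table(monthly$year) == 12L))
    monthly <- monthly %>%
      filter(.data$year %in% as.integer(full_years)) %>%
      thornthwaite_pet(latitude = latitude)
  }
  sp <- spei(monthly, scale = spei_scale, calibration = spei_calibration)
  sp_mon <- sp %>%
    mutate(variable = "spei3", window = MONTH_LABELS[.data$month]) %>%
    select("year", "variable", "window", value = "spei")
  sp_vp <- sp %>%
    filter(.data$month %in% 4:9) %>%
    group_by(.data$year) %>%
    summarise(value = mean(.data$spei), .groups = "drop") %>%
    mutate(variable = "spei3", window = "VP")

  out <- bind_rows(long, sp_mon, sp_vp)

  # keep only the defined (variable, window-kind) pairs
  keep <- purrr::map2(
    names(INDEX_WINDOWS), INDEX_WINDOWS,
    function(v, kinds) {
      w <- c(
        if ("month" %in% kinds) MONTH_LABELS,
        setdiff(kinds, "month")
      )
      tibble(variable = v, window = w)
    }
  ) %>% bind_rows()
  out %>%
    dplyr::inner_join(keep, by = c("variable", "window")) %>%
    filter(!(.data$variable == "vpd" & is.na(.data$value) & !has_rh)) %>%
    arrange(.data$year, .data$variable, .data$window)
}

days_in_month <- function(year, month) {
  vapply(seq_along(year), function(i) {
    w <- month_window(year[i], month[i])
    window_length(w)
  }, numeric(1))
}

window_length <- function(window) {
  as.numeric(window$end - window$start) + 1
}

#' Identify climatic stress years
#'
#' A year is flagged as a climatic stress event when its vegetation-period
#' mean temperature is at or above the 90th percentile and/or its
#' vegetation-period precipitation sum is at or below the 10th percentile
#' of the study years (percentiles by linear interpolation between order
#' statistics, `quantile(type = 7)`; ties at the threshold flag all tied
#' years). Confirmation flags mark VP values of hot days, heat sum and VPD
#' at/above their 90th percentile, rain days at/below the 10th, and VP
#' spei3 < -1.
#'
#' @param indices A climate index table from [climate_indices()].
#' @param study_years Years over which percentiles are computed (default:
#'   all years with a VP value). Fewer than 10 raises a warning.
#' @return A tibble, one row per study year: the VP values, primary flags
#'   `hot_year` and `dry_year`, `stress` (either primary), and the
#'   confirmation flags.
#' @export
detect_stress_years <- function(indices, study_years = NULL) {
  vp <- indices %>%
    filter(.data$window == "VP") %>%
    tidyr::pivot_wider(
      id_cols = "year",
      names_from = "variable", values_from = "value"
    )
  if (!is.null(study_years)) vp <- filter(vp, .data$year %in% study_years)
  vp <- filter(vp, !is.na(.data$tmean), !is.na(.data$ppt))
  if (nrow(vp) < 10L) {
    warn(sprintf(
      "Only %d study years: stress-year percentiles are unstable.", nrow(vp)
    ))
  }
  p90 <- function(x) quantile(x, 0.90, names = FALSE, type = 7, na.rm = TRUE)
  p10 <- function(x) quantile(x, 0.10, names = FALSE, type = 7, na.rm = TRUE)
  maybe <- function(col) if (col %in% names(vp)) vp[[col]] else NA_real_
  nhd <- maybe("nhd"); hs <- maybe("hs"); vpdv <- maybe("vpd")
  nrd <- maybe("nrd"); sp3 <- maybe("spei3")
  flag_ge <- function(x) if (all(is.na(x))) NA else x >= p90(x)
  flag_le <- function(x) if (all(is.na(x))) NA else x <= p10(x)
  vp %>%
    mutate(
      hot_year = .data$tmean >= p90(.data$tmean),
      dry_year = .data$ppt <= p10(.data$ppt),
      stress = .data$hot_year | .data$dry_year,
      confirm_nhd = flag_ge(nhd),
      confirm_hs = flag_ge(hs),
      confirm_vpd = flag_ge(vpdv),
      confirm_nrd = flag_le(nrd),
      confirm_spei = if (all(is.na(sp3))) NA else sp3 < -1
    ) %>%
    arrange(.data$year)
}
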