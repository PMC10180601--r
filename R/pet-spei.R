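# Thornthwaite potential evapotranspiration and the standardised
# precipitation-evapotranspiration index (SPEI) on the monthly water
# balance D = PPT - PET. SPEI fits a 3-parameter log-logistic distribution
# per calendar month by unbiased probability-weighted moments over the
# calibration years and maps the CDF value to a standard normal deviate.

#' Thornthwaite monthly potential evapotranspiration
#'
#' Temperature-and-latitude based PET: annual heat index
#' \eqn{I = \sum_m (T_m/5)^{1.514}} over months with \eqn{T_m > 0};
#' exponent \eqn{a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 +
#' 1.792\times10^{-2} I + 0.49239}; uncorrected
#' \eqn{PET_m = 16 (10 T_m / I)^a} mm, scaled by the day-length and
#' month-length correction \eqn{L_m = (N_m/12)(d_m/30)} for the site
#' latitude. Months with \eqn{T_m \le 0} get PET 0; very warm months
#' (> 26.5 C) use the standard hot-month polynomial.
#'
#' @param monthly A table with columns `year`, `month`, `tmean` (monthly
#'   mean temperature, C), whole calendar years.
#' @param latitude Site latitude in decimal degrees.
#' @param correction Optional explicit length-12 vector of monthly
#'   corrections \eqn{L_m} overriding the latitude computation (useful for
#'   controlled checks; `L = 1` gives the uncorrected formula).
#' @return The input tibble with a `pet` column (mm/month).
#' @export
thornthwaite_pet <- function(monthly, latitude, correction = NULL) {
  monthly <- as_tibble(monthly) %>% arrange(.data$year, .data$month)
  if (!all(table(monthly$year) == 12L)) {
    abort("`monthly` must contain whole calendar years (12 months each).")
  }
  L <- if (is.null(correction)) {
    daylength_correction(latitude)
  } else {
    if (length(correction) != 12L) abort("`correction` must have length 12.")
    correction
  }
  monthly %>%
    group_by(.data$year) %>%
    mutate(pet = thornthwaite_year(.data$tmean, .data$month, L)) %>%
    ungroup()
}

thornthwaite_year <- function(tmean, month, L) {
  i_m <- ifelse(tmean > 0, (tmean / 5)^1.514, 0)
  I <- sum(i_m)
  if (I == 0) abort("Heat index is zero: all months <= 0 C.")
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  pet <- numeric(length(tmean))
  warm <- tmean > 26.5
  mild <- tmean > 0 & !warm
  pet[mild] <- 16 * (10 * tmean[mild] / I)^a
  pet[warm] <- -415.85 + 32.24 * tmean[warm] - 0.43 * tmean[warm]^2
  pet * L[month]
}

# Mean day length per month (hours) / 12, times month length / 30.
daylength_correction <- function(latitude) {
  phi <- latitude * pi / 180
  mid <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  ndays <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  delta <- 0.4093 * sin(2 * pi * (284 + mid) / 365)
  cosw <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  N <- 24 * acos(cosw) / pi
  (N / 12) * (ndays / 30)
}

#' Standardised precipitation-evapotranspiration index (SPEI)
#'
#' The k-month backward rolling sum of the monthly water balance
#' D = PPT - PET is assigned to the ending month; per calendar month a
#' 3-parameter log-logistic distribution is fitted by unbiased
#' probability-weighted moments over the calibration years and the CDF
#' value is transformed to a standard normal deviate. By construction the
#' index has mean ~0 and sd ~1 per calendar month over the calibration
#' period.
#'
#' @param monthly A table with columns `year`, `month`, `ppt`, `pet`
#'   (mm/month), consecutive months.
#' @param scale Aggregation scale in months (default 3, i.e. spei3).
#' @param calibration Integer vector of calibration years (default: all
#'   years present). Fewer than 30 raises a warning.
#' @return A tibble `year`, `month`, `d` (monthly balance), `d_roll`
#'   (k-month sum), `spei`, `drought_class`.
#' @export
spei <- function(monthly, scale = 3L, calibration = NULL) {
  monthly <- as_tibble(monthly) %>% arrange(.data$year, .data$month)
  idx <- monthly$year * 12L + monthly$month
  if (any(diff(idx) != 1L)) abort("`monthly` must be consecutive months.")
  if (is.null(calibration)) calibration <- unique(monthly$year)
  if (length(calibration) < 30L) {
    warn(sprintf(
      "Only %d calibration years; >= 30 are recommended for stable SPEI.",
      length(calibration)
    ))
  }
  d <- monthly$ppt - monthly$pet
  n <- length(d)
  d_roll <- rep(NA_real_, n)
  if (n >= scale) {
    cs <- cumsum(d)
    d_roll[scale:n] <- cs[scale:n] - c(0, cs)[seq(1, n - scale + 1)]
  }
  out <- monthly %>%
    mutate(d = d, d_roll = d_roll, spei = NA_real_)
  for (m in 1:12) {
    rows <- which(out$month == m & !is.na(out$d_roll))
    cal <- rows[out$year[rows] %in% calibration]
    if (length(cal) < 4L) next
    xs <- out$d_roll[cal]
    if (sd(xs) == 0) {
      abort(sprintf("Degenerate (constant) water balance in month %d.", m))
    }
    par <- loglogistic_pwm(xs)
    p <- loglogistic_cdf(out$d_roll[rows], par)
    out$spei[rows] <- qnorm(pmin(pmax(p, 1e-8), 1 - 1e-8))
  }
  out %>% mutate(drought_class = classify_drought(.data$spei))
}

# Unbiased probability-weighted moments w_s = E[X (1-F)^s] of the sample,
# then the standard log-logistic parameterisation (shape beta, scale
# alpha, location gamma).
loglogistic_pwm <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((n - i) / (n - 1) * x) / n
  b2 <- sum((n - i) * (n - i - 1) / ((n - 1) * (n - 2)) * x) / n
  beta <- (2 * b1 - b0) / (6 * b1 - b0 - 6 * b2)
  g1 <- gamma(1 + 1 / beta)
  g2 <- gamma(1 - 1 / beta)
  alpha <- (b0 - 2 * b1) * beta / (g1 * g2)
  gam <- b0 - alpha * g1 * g2
  list(alpha = alpha, beta = beta, gamma = gam)
}

loglogistic_cdf <- function(x, par) {
  z <- (x - par$gamma) / par$alpha
  p <- ifelse(z > 0, 1 / (1 + z^(-par$beta)), 0)
  p
}

#' Drought severity class from SPEI
#'
#' Moderate: -1.49 to -1.00; severe: -1.99 to -1.50; extreme: <= -2.00;
#' otherwise none.
#'
#' @param spei3 Numeric SPEI values (NA allowed).
#' @return A factor with levels none < moderate < severe < extreme.
#' @export
classify_drought <- function(spei3) {
  cls <- dplyr::case_when(
    is.na(spei3) ~ NA_character_,
    spei3 <= -2.00 ~ "extreme",
    spei3 <= -1.50 ~ "severe",
    spei3 <= -1.00 ~ "moderate",
    TRUE ~ "none"
  )
  factor(cls, levels = c("none", "moderate", "severe", "extreme"), ordered = TRUE)
}

#' Monthly climate summaries from daily records
#'
#' Helper producing the monthly `tmean`, `ppt` (and `pet` when present)
#' table needed by [thornthwaite_pet()] and [spei()].
#'
#' @param daily Daily climate table (`date`, `tmean`, `ppt`, optional
#'   `pet`).
#' @return A tibble `year`, `month`, `tmean`, `ppt` (and `pet`).
#' @export
monthly_climate <- function(daily) {
  out <- daily %>%
    mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    ) %>%
    group_by(.data$year, .data$month) %>%
    summarise(
      tmean = mean(.data$tmean),
      ppt = sum(.data$ppt),
      pet = if ("pet" %in% names(daily)) sum(.data$pet) else NA_real_,
      .groups = "drop"
    )
  if (all(is.na(out$pet))) out$pet <- NULL
  out
}
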