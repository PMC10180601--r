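# Synthetic daily climate and multi-species ring-width data with known
# ground truth, shaped like a ~26-year Central European conifer comparison:
# site normals around 8.2 C / 741 mm a^-1 (13.9 C / 399 mm over the
# vegetation period), 2 cores per tree, a negative-exponential age trend,
# species-specific monthly precipitation drivers and engineered hot-dry
# years. Every pipeline stage has a recovery test against these defaults.

#' Configuration for the synthetic daily-climate generator
#'
#' Defaults emulate the Bayreuth study site: annual mean temperature
#' 8.2 C with seasonal amplitude 9.4 C (vegetation-period mean ~13.9 C),
#' AR(1) day-to-day temperature noise, occurrence/gamma precipitation
#' tuned to 741 mm a^-1 (399 mm April-September), and four engineered
#' hot-dry years (2003, 2012, 2015, 2018) realised as a vegetation-period
#' temperature offset plus a precipitation multiplier.
#'
#' @param years Calendar years to simulate.
#' @param seed Integer seed.
#' @param t_mean,t_amp Annual mean and seasonal (cosine) amplitude of
#'   daily mean temperature, C; the seasonal peak sits at day `t_peak_doy`.
#' @param t_peak_doy Day of year of the temperature peak (default 200).
#' @param t_ar1,t_sd AR(1) coefficient and stationary (day-to-day) sd of
#'   the daily temperature anomaly, C.
#' @param diurnal_half Half of the diurnal range: `tmax = tmean +
#'   diurnal_half`, `tmin = tmean - diurnal_half` (default 6 C).
#' @param ppt_prob Daily precipitation occurrence probability.
#' @param ppt_mean_vp,ppt_mean_other Mean wet-day amount (mm) inside and
#'   outside April-September.
#' @param ppt_shape Gamma shape of wet-day amounts.
#' @param rh_base,rh_slope,rh_sd Relative-humidity model: `rh_base` minus
#'   `rh_slope` per degree of temperature anomaly plus Gaussian noise,
#'   clamped to \[25, 100\] %.
#' @param drought_years A data frame `year`, `t_offset` (C added to VP
#'   temperatures), `ppt_mult` (multiplier in (0, 1] on VP precipitation).
#' @return A list of class `climate_gen_config`.
#' @export
climate_gen_config <- function(years = 1994:2019, seed = 1L,
                               t_mean = 8.2, t_amp = 9.4, t_peak_doy = 200,
                               t_ar1 = 0.7, t_sd = 3.5, diurnal_half = 6,
                               ppt_prob = 0.45, ppt_mean_vp = 4.85,
                               ppt_mean_other = 4.17, ppt_shape = 0.9,
                               rh_base = 78, rh_slope = 1.5, rh_sd = 6,
                               drought_years = default_drought_years()) {
  drought_years <- as_tibble(drought_years)
  if (nrow(drought_years) &&
    any(drought_years$ppt_mult <= 0 | drought_years$ppt_mult > 1)) {
    abort("Drought `ppt_mult` must lie in (0, 1].")
  }
  structure(
    list(
      years = years, seed = as.integer(seed),
      t_mean = t_mean, t_amp = t_amp, t_peak_doy = t_peak_doy,
      t_ar1 = t_ar1, t_sd = t_sd, diurnal_half = diurnal_half,
      ppt_prob = ppt_prob, ppt_mean_vp = ppt_mean_vp,
      ppt_mean_other = ppt_mean_other, ppt_shape = ppt_shape,
      rh_base = rh_base, rh_slope = rh_slope, rh_sd = rh_sd,
      drought_years = drought_years
    ),
    class = "climate_gen_config"
  )
}

#' @rdname climate_gen_config
#' @export
default_drought_years <- function() {
  tibble(
    year = c(2003L, 2012L, 2015L, 2018L),
    t_offset = c(3.0, 0.8, 1.2, 3.0),
    ppt_mult = c(0.45, 0.80, 0.50, 0.45)
  )
}

#' Simulate daily climate records
#'
#' @param config A [climate_gen_config()].
#' @param seed Seed override (default: the config's seed).
#' @return A daily tibble `date`, `tmin`, `tmax`, `tmean`, `ppt`, `rh`,
#'   with the drought-year table attached as
#'   `attr(, "drought_years")`.
#' @export
simulate_climate <- function(config = climate_gen_config(), seed = NULL) {
  cfg <- config
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  dates <- seq(
    as.Date(sprintf("%04d-01-01", min(cfg$years))),
    as.Date(sprintf("%04d-12-31", max(cfg$years))),
    by = "1 day"
  )
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  year <- as.integer(format(dates, "%Y"))
  month <- as.integer(format(dates, "%m"))
  in_vp <- month %in% 4:9
  local_seed(seed, {
    base <- cfg$t_mean + cfg$t_amp * cos(2 * pi * (doy - cfg$t_peak_doy) / 365.25)
    # AR(1) anomaly scaled so t_sd is its stationary (day-to-day) sd
    noise <- if (cfg$t_sd == 0) {
      numeric(n)
    } else {
      as.numeric(stats::arima.sim(list(ar = cfg$t_ar1), n, sd = cfg$t_sd)) *
        sqrt(1 - cfg$t_ar1^2)
    }
    tmean <- base + noise
    wet <- stats::runif(n) < cfg$ppt_prob
    amt_mean <- ifelse(in_vp, cfg$ppt_mean_vp, cfg$ppt_mean_other)
    amt <- stats::rgamma(n, shape = cfg$ppt_shape,
      scale = amt_mean / cfg$ppt_shape
    )
    ppt <- ifelse(wet, amt, 0)
    for (i in seq_len(nrow(cfg$drought_years))) {
      dy <- cfg$drought_years[i, ]
      sel <- year == dy$year & in_vp
      tmean[sel] <- tmean[sel] + dy$t_offset
      ppt[sel] <- ppt[sel] * dy$ppt_mult
    }
    rh <- cfg$rh_base - cfg$rh_slope * (tmean - base) -
      0.8 * pmax(tmean - 20, 0) + stats::rnorm(n, sd = cfg$rh_sd)
    rh <- pmin(pmax(rh, 25), 100)
    out <- tibble(
      date = dates,
      tmin = tmean - cfg$diurnal_half,
      tmax = tmean + cfg$diurnal_half,
      tmean = tmean, ppt = ppt, rh = rh
    )
    structure(out, drought_years = cfg$drought_years, class = class(out))
  })
}

#' Configuration for the synthetic forest generator
#'
#' Defaults mimic the study layout: three species with 27/17/13 trees and
#' two cores each, a negative-exponential age trend around 4-5 mm a^-1,
#' and species-specific precipitation drivers (current February;
#' June-August; July). The driver effect size `beta` (log ring width per
#' sd of the driver) combined with the shared non-climatic year noise
#' `sd_common` sets the true climate-growth correlation, ~0.6 at the
#' defaults. Drought years multiply the event-year ring width by the
#' species' `drought_mult`.
#'
#' @param species A data frame `species`, `n_trees`, `beta`,
#'   `driver_variable` (currently `"ppt"`), `driver_months` (list column
#'   of month vectors, current year), `drought_mult`.
#' @param cores_per_tree Number of cores per tree (default 2).
#' @param age_a,age_tau,age_c Negative-exponential age trend
#'   `a exp(-(t-1)/tau) + c` in mm.
#' @param sd_common Sd of the shared (all trees of a species) log-scale
#'   year effect not explained by the driver.
#' @param sd_tree Sd of the per-tree-per-year log effect.
#' @param sd_core Sd of the per-core log noise.
#' @param tree_scale_sd Sd of the per-tree lognormal level (tree-to-tree
#'   vigor differences).
#' @param seed Integer seed.
#' @return A list of class `forest_gen_config`.
#' @export
forest_gen_config <- function(species = default_species_config(),
                              cores_per_tree = 2L,
                              age_a = 3, age_tau = 12, age_c = 3,
                              sd_common = 0.2, sd_tree = 0.15,
                              sd_core = 0.1, tree_scale_sd = 0.1,
                              seed = 1L) {
  species <- as_tibble(species)
  if (any(species$n_trees < 2L)) abort("Each species needs n_trees >= 2.")
  structure(
    list(
      species = species, cores_per_tree = as.integer(cores_per_tree),
      age_a = age_a, age_tau = age_tau, age_c = age_c,
      sd_common = sd_common, sd_tree = sd_tree, sd_core = sd_core,
      tree_scale_sd = tree_scale_sd, seed = as.integer(seed)
    ),
    class = "forest_gen_config"
  )
}

#' @rdname forest_gen_config
#' @export
default_species_config <- function() {
  tibble(
    species = c("C. libani", "P. abies", "P. sylvestris"),
    n_trees = c(27L, 17L, 13L),
    beta = c(0.17, 0.17, 0.17),
    driver_variable = "ppt",
    driver_months = list(2L, 6:8, 7L),
    drought_mult = c(0.85, 0.60, 0.70)
  )
}

#' Simulate a multi-species forest of ring-width cores
#'
#' Ring width of core c of tree i in year t:
#' `age(t) * scale_i * exp(beta z_t + e_year + e_tree + e_core) * mult_t`,
#' where `z_t` is the species' standardised climate driver (monthly
#' precipitation over its driver months), `mult_t` the species drought
#' multiplier in engineered drought years, and the log-normal noise terms
#' keep widths positive. Cores of a tree share everything but `e_core`.
#'
#' @param config A [forest_gen_config()].
#' @param climate Daily climate from [simulate_climate()] (drought years
#'   are read from its attribute unless `drought_years` is given).
#' @param years Ring years to generate (default: the climate's years).
#' @param drought_years Optional override, a data frame with a `year`
#'   column.
#' @param seed Seed override (default: the config's seed).
#' @return A core table `tree_id`, `core_id`, `species`, `year`,
#'   `width_mm` with the generating truth in `attr(, "ground_truth")`
#'   (species table, drought years and multipliers, driver z-scores).
#' @export
simulate_forest <- function(config = forest_gen_config(), climate,
                            years = NULL, drought_years = NULL, seed = NULL) {
  cfg <- config
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  monthly <- monthly_climate(climate)
  if (is.null(years)) years <- sort(unique(monthly$year))
  if (is.null(drought_years)) {
    dy <- attr(climate, "drought_years")
    drought_years <- if (is.null(dy)) integer(0) else dy$year
  } else if (is.data.frame(drought_years)) {
    drought_years <- drought_years$year
  }
  t_rel <- seq_along(years)
  age <- cfg$age_a * exp(-(t_rel - 1) / cfg$age_tau) + cfg$age_c

  drivers <- purrr::pmap(cfg$species, function(species, driver_variable,
                                               driver_months, ...) {
    v <- monthly %>%
      filter(.data$month %in% driver_months, .data$year %in% years) %>%
      group_by(.data$year) %>%
      summarise(value = sum(.data[[driver_variable]]), .groups = "drop") %>%
      arrange(.data$year)
    if (!all(v$year == years)) abort("Climate does not cover all ring years.")
    as.numeric(scale(v$value))
  })
  names(drivers) <- cfg$species$species

  ny <- length(years)
  out <- local_seed(seed, {
    purrr::pmap(
      cbind(cfg$species, sp_idx = seq_len(nrow(cfg$species))),
      function(species, n_trees, beta, drought_mult, sp_idx, ...) {
        z <- drivers[[species]]
        mult <- ifelse(years %in% drought_years, drought_mult, 1)
        e_year <- stats::rnorm(ny, sd = cfg$sd_common)
        tree_log <- log(age) + beta * z + log(mult) + e_year
        purrr::map(seq_len(n_trees), function(i) {
          scale_i <- stats::rnorm(1, sd = cfg$tree_scale_sd)
          e_tree <- stats::rnorm(ny, sd = cfg$sd_tree)
          purrr::map(seq_len(cfg$cores_per_tree), function(k) {
            e_core <- stats::rnorm(ny, sd = cfg$sd_core)
            tibble(
              tree_id = sprintf("S%d_T%02d", sp_idx, i),
              core_id = LETTERS[k],
              species = species,
              year = years,
              width_mm = exp(tree_log + scale_i + e_tree + e_core)
            )
          }) %>% bind_rows()
        }) %>% bind_rows()
      }
    ) %>% bind_rows()
  })
  if (any(out$width_mm <= 0)) abort("Configuration produced non-positive widths.")
  structure(out,
    ground_truth = list(
      species = cfg$species,
      drought_years = drought_years,
      drivers = drivers,
      years = years,
      age_trend = age
    ),
    class = class(out)
  )
}
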