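# Age-trend removal and growth-index chronologies. The detrending spline is
# a penalised cubic smoothing spline on the annual grid whose smoothing
# parameter is derived from a target frequency response: amplitude
# `amplitude` (50 % by default) at a wavelength of `cutoff_fraction` (67 %)
# of the series length (Cook-Peters parameterisation).

#' Fit a frequency-calibrated cubic smoothing spline
#'
#' Solves the discrete penalised least-squares problem
#' \deqn{\min_g \sum_t (x_t - g_t)^2 + \lambda \sum_t (\Delta^2 g_t)^2}
#' with the smoothing parameter chosen analytically so that the filter's
#' frequency-response amplitude equals `amplitude` at the wavelength
#' `cutoff_fraction * length(x)` years:
#' \deqn{\lambda = \frac{1-a}{a}\,
#'   \frac{\cos 2\pi f + 2}{6\,(\cos 2\pi f - 1)^2},\qquad f = 1/p.}
#' Low-frequency (age/size) trend is captured by the fit; interannual
#' variation passes into the ratio indices.
#'
#' @param x Annual series (numeric, length >= 10, finite and positive).
#' @param cutoff_fraction Cutoff wavelength as a fraction of the series
#'   length (default 0.67).
#' @param amplitude Target frequency-response amplitude at the cutoff
#'   (default 0.5).
#' @return An object of class `spline_fit`: list with `x`, `fitted`,
#'   `lambda`, `cutoff_years`, `amplitude`.
#' @examples
#' fit <- fit_spline(5 + 0.01 * (1:60) + rnorm(60, sd = 0.1))
#' @export
fit_spline <- function(x, cutoff_fraction = 0.67, amplitude = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) abort("Series too short for spline detrending (need >= 10).")
  if (!all(is.finite(x))) abort("`x` must be finite.")
  if (cutoff_fraction <= 0) abort("`cutoff_fraction` must be positive.")
  if (amplitude <= 0 || amplitude >= 1) abort("`amplitude` must be in (0, 1).")
  p <- cutoff_fraction * n
  lambda <- spline_lambda(p, amplitude)
  fitted <- solve_penalised(x, lambda)
  structure(
    list(
      x = x, fitted = fitted, lambda = lambda,
      cutoff_years = p, amplitude = amplitude
    ),
    class = "spline_fit"
  )
}

# Cook-Peters 1981 criterion: frequency-response amplitude a at period p.
spline_lambda <- function(period, amplitude) {
  ct <- cos(2 * pi / period)
  ((1 - amplitude) / amplitude) * (ct + 2) / (6 * (ct - 1)^2)
}

solve_penalised <- function(x, lambda) {
  n <- length(x)
  D <- diff(diag(n), differences = 2)
  as.numeric(solve(diag(n) + lambda * crossprod(D), x))
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf(
    "<spline_fit> n = %d, cutoff = %.1f yr, amplitude = %.2f, lambda = %.3g\n",
    length(x$x), x$cutoff_years, x$amplitude, x$lambda
  ))
  invisible(x)
}

#' Ratio growth indices from a fitted age trend
#'
#' The dimensionless growth index is the ratio of the measured ring width to
#' the spline-fitted value, oscillating around 1.0. Non-positive fitted
#' values abort (they would flip or explode the index).
#'
#' @param raw Numeric raw series (same length as the fit).
#' @param fit A `spline_fit`, or a numeric vector of fitted values.
#' @return Numeric vector of indices.
#' @export
growth_indices <- function(raw, fit) {
  fitted <- if (inherits(fit, "spline_fit")) fit$fitted else as.numeric(fit)
  raw <- as.numeric(raw)
  if (length(raw) != length(fitted)) {
    abort("`raw` and fitted values differ in length.")
  }
  bad <- which(fitted <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Fitted value <= 0 at position %d; cannot form ratio indices.", bad[[1]]
    ))
  }
  raw / fitted
}

#' Tukey's biweight robust mean
#'
#' Iteratively reweighted location estimate with weights
#' \eqn{(1-u^2)^2} for \eqn{|u| < 1}, \eqn{u_i = (x_i - M)/(c \cdot MAD)},
#' which zeroes the influence of gross outliers. If the MAD is zero the
#' median is returned.
#'
#' @param values Numeric vector with at least one finite value.
#' @param c Biweight tuning constant (default 9, conventional for
#'   chronology building).
#' @param tol Convergence tolerance on the location (default 1e-6).
#' @param max_iter Iteration cap (default 50).
#' @return The robust mean (scalar).
#' @examples
#' biweight_mean(c(0.8, 0.9, 1.0, 1.1, 1.2, 5.0))
#' @export
biweight_mean <- function(values, c = 9, tol = 1e-6, max_iter = 50L) {
  x <- values[is.finite(values)]
  if (!length(x)) abort("`values` has no finite entries.")
  if (length(x) == 1L) return(x)
  m <- median(x)
  s <- c * mad(x, center = m, constant = 1)
  if (s == 0) return(m)
  for (i in seq_len(max_iter)) {
    u <- (x - m) / s
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Rbar and the expressed population signal (EPS)
#'
#' `rbar` is the mean of all pairwise Pearson correlations between the
#' trees' growth-index series over each pair's common years; the expressed
#' population signal is the Wigley form
#' \deqn{EPS = \frac{n\,\bar r}{n\,\bar r + (1 - \bar r)}}
#' with `n` the mean per-year sample depth. EPS > 0.85 is the conventional
#' threshold for an acceptable chronology.
#'
#' @param indices A data frame `tree_id`, `year`, `index` (one series per
#'   tree).
#' @param min_overlap Minimum number of common years a pair must share to
#'   enter rbar (default 10).
#' @return A list with `rbar`, `eps`, `n` (mean sample depth) and
#'   `n_pairs`.
#' @export
chronology_stats <- function(indices, min_overlap = 10L) {
  indices <- as_tibble(indices)
  wide <- tidyr::pivot_wider(
    indices[c("tree_id", "year", "index")],
    names_from = "tree_id", values_from = "index"
  ) %>% arrange(.data$year)
  m <- as.matrix(wide[-1])
  k <- ncol(m)
  if (k < 2L) abort("Need at least two index series.")
  cors <- c()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      ok <- stats::complete.cases(m[, c(i, j)])
      if (sum(ok) >= min_overlap) {
        cors <- c(cors, cor(m[ok, i], m[ok, j]))
      }
    }
  }
  if (!length(cors)) abort("No tree pair has sufficient overlap.")
  rbar <- mean(cors)
  depth <- rowSums(!is.na(m))
  n <- mean(depth[depth > 0])
  list(rbar = rbar, eps = eps_wigley(rbar, n), n = n, n_pairs = length(cors))
}

#' @rdname chronology_stats
#' @param rbar Mean inter-series correlation.
#' @param n (Mean) number of trees.
#' @export
eps_wigley <- function(rbar, n) {
  n * rbar / (n * rbar + (1 - rbar))
}

#' Build a growth index chronology (GIC)
#'
#' Each tree's RGS is spline-detrended ([fit_spline()]) and converted to
#' ratio indices ([growth_indices()]); the species chronology is Tukey's
#' biweight robust mean of the indices across trees, year by year, for
#' years with at least `min_depth` trees. Rbar and EPS are attached.
#'
#' @param trees Per-tree series table (`tree_id`, `species`, `year`,
#'   `width_mm`), one species.
#' @param cutoff_fraction,amplitude Spline calibration, see [fit_spline()].
#' @param min_depth Minimum trees per retained year (default 2).
#' @param min_overlap Passed to [chronology_stats()].
#' @return A tibble `year`, `index`, `depth` of class `gic` with attributes
#'   `species`, `rbar`, `eps`, `n_trees`, `mean_depth` and the per-tree
#'   index table in `attr(, "tree_indices")`; `glance()` summarises them.
#' @export
build_gic <- function(trees, cutoff_fraction = 0.67, amplitude = 0.5,
                      min_depth = 2L, min_overlap = 10L) {
  trees <- check_tree_table(trees)
  species <- unique(trees$species)
  if (length(species) != 1L) abort("`build_gic()` expects a single species.")
  if (n_distinct(trees$tree_id) < 2L) abort("Need at least two trees.")

  idx <- trees %>%
    arrange(.data$tree_id, .data$year) %>%
    group_by(.data$tree_id) %>%
    dplyr::group_modify(function(d, key) {
      if (any(diff(d$year) != 1L)) {
        abort(sprintf("Tree %s has non-consecutive years.", key$tree_id))
      }
      fit <- fit_spline(d$width_mm, cutoff_fraction, amplitude)
      tibble(year = d$year, index = growth_indices(d$width_mm, fit))
    }) %>%
    ungroup()

  chron <- idx %>%
    group_by(.data$year) %>%
    summarise(
      index = biweight_mean(.data$index),
      depth = dplyr::n(),
      .groups = "drop"
    ) %>%
    filter(.data$depth >= min_depth) %>%
    arrange(.data$year)

  stats <- chronology_stats(idx, min_overlap = min_overlap)
  structure(chron,
    species = species,
    rbar = stats$rbar, eps = stats$eps,
    n_trees = n_distinct(trees$tree_id),
    mean_depth = stats$n,
    ar1 = lag1_autocorrelation(chron$index),
    tree_indices = idx,
    class = c("gic", class(chron))
  )
}

#' @export
glance.gic <- function(x, ...) {
  tibble(
    species = attr(x, "species"),
    n_trees = attr(x, "n_trees"),
    first_year = min(x$year),
    last_year = max(x$year),
    mean_depth = attr(x, "mean_depth"),
    rbar = attr(x, "rbar"),
    eps = attr(x, "eps"),
    ar1 = attr(x, "ar1")
  )
}

#' @export
tidy.gic <- function(x, ...) {
  as_tibble(unclass(x)[c("year", "index", "depth")])
}

#' Write GIC summary statistics to JSON
#'
#' @param gic A `gic` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gic_stats_json <- function(gic, path) {
  jsonlite::write_json(
    as.list(glance(gic)),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
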