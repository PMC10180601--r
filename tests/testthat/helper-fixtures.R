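# Small in-code fixtures shared across test files.

make_cores <- function(tree_id = "T1", species = "P. abies",
                       years = 2000:2001, widths_a = c(2, 2),
                       widths_b = widths_a) {
  dplyr::bind_rows(
    tibble::tibble(
      tree_id = tree_id, core_id = "A", species = species,
      year = years, width_mm = widths_a
    ),
    tibble::tibble(
      tree_id = tree_id, core_id = "B", species = species,
      year = years, width_mm = widths_b
    )
  )
}

# deterministic multi-tree table: one species, consecutive years
make_trees <- function(n_trees, years, width_fn) {
  purrr::map(seq_len(n_trees), function(i) {
    tibble::tibble(
      tree_id = sprintf("T%02d", i), species = "P. abies",
      year = years, width_mm = width_fn(i, years)
    )
  }) |> dplyr::bind_rows()
}

# daily climate frame with constant values, optionally overridden
make_daily <- function(years = 1995, tmean = 10, tmin = tmean - 5,
                       tmax = tmean + 5, ppt = 0, rh = 70) {
  dates <- seq(
    as.Date(sprintf("%04d-01-01", min(years))),
    as.Date(sprintf("%04d-12-31", max(years))),
    by = "1 day"
  )
  tibble::tibble(
    date = dates, tmin = tmin, tmax = tmax, tmean = tmean,
    ppt = ppt, rh = rh
  )
}

# independent brute-force biweight oracle (plain loop, no shortcuts)
biweight_oracle <- function(x, c = 9, iters = 200) {
  m <- stats::median(x)
  s <- c * stats::median(abs(x - stats::median(x)))
  if (s == 0) return(m)
  for (i in seq_len(iters)) {
    u <- (x - m) / s
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    m <- sum(w * x) / sum(w)
  }
  m
}

# projection-based spline gain oracle: fit a constant + sinusoid of the
# given period, regress the fitted values on the sinusoid
spline_gain <- function(n, period, cutoff_fraction = 0.67, amplitude = 0.5,
                        phase = 0) {
  t <- seq_len(n)
  s <- sin(2 * pi * t / period + phase)
  fit <- fit_spline(10 + s, cutoff_fraction, amplitude)$fitted
  sum((fit - mean(fit)) * (s - mean(s))) / sum((s - mean(s))^2)
}

# a fresh path inside a test-scoped temporary directory
withr_local_file <- function(name) {
  file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
}
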