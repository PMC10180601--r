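# Bootstrapped Pearson correlation functions between a growth-index
# chronology and monthly/seasonal climate variables. The screened month
# window runs from previous-year September to current-year September;
# previous-year months are labelled in lower case ("sep"), current-year
# months in capitals ("SEP"), mirroring the field's table convention.

#' Build the year-aligned climate/growth design matrix
#'
#' One row per year in which the chronology and the climate record
#' overlap; one column per (variable, window) pair. Previous-year months
#' are lagged: column `ppt.feb` of row year y holds February of y - 1.
#' Columns that contain missing values or have zero variance are dropped
#' with a warning.
#'
#' @param gic A `gic` object (or tibble `year`, `index`).
#' @param indices Climate index table from [climate_indices()].
#' @param prev_months Previous-year months to include (default Sep-Dec).
#' @param cur_months Current-year months to include (default Jan-Sep).
#' @param seasonal Include the VP and PW aggregates (default `TRUE`).
#' @return A tibble: `year`, `gic`, then one numeric column per
#'   (variable, window).
#' @export
build_design_matrix <- function(gic, indices, prev_months = 9:12,
                                cur_months = 1:9, seasonal = TRUE) {
  chron <- as_tibble(unclass(gic))[c("year", "index")]
  names(chron)[2] <- "gic"

  lagged <- bind_rows(
    indices %>%
      filter(.data$window %in% MONTH_LABELS[prev_months]) %>%
      mutate(
        year = .data$year + 1L,
        label = tolower(.data$window)
      ),
    indices %>%
      filter(.data$window %in% MONTH_LABELS[cur_months]) %>%
      mutate(label = .data$window),
    if (seasonal) {
      indices %>%
        filter(.data$window %in% c("VP", "PW")) %>%
        mutate(label = .data$window)
    }
  ) %>%
    mutate(column = paste(.data$variable, .data$label, sep = "."))

  wide <- lagged %>%
    tidyr::pivot_wider(
      id_cols = "year",
      names_from = "column", values_from = "value"
    )
  out <- dplyr::inner_join(chron, wide, by = "year") %>% arrange(.data$year)
  # leading/trailing years without full coverage (typically the first year,
  # whose previous-year months precede the climate record) are trimmed
  complete <- stats::complete.cases(out)
  keep <- cumsum(complete) > 0 & rev(cumsum(rev(complete))) > 0
  out <- out[keep, ]
  if (nrow(out) < 15L) {
    abort(sprintf(
      "Only %d overlapping years between chronology and climate (need >= 15).",
      nrow(out)
    ))
  }
  vals <- out[-(1:2)]
  bad <- vapply(
    vals, function(v) anyNA(v) || sd(v) == 0, logical(1)
  )
  if (any(bad)) {
    warn(sprintf(
      "Dropping %d design column(s) with missing values or zero variance: %s",
      sum(bad), paste(head(names(vals)[bad], 8), collapse = ", ")
    ))
    out <- out[c(TRUE, TRUE, !bad)]
  }
  out
}

#' Bootstrapped Pearson correlation of a paired sample
#'
#' The reported `r` is the full-sample Pearson coefficient; `n_boot`
#' resamples of the pairs (with replacement) give a percentile confidence
#' interval, and the correlation is called significant when that interval
#' excludes zero. Fully reproducible given `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param x,y Paired numeric vectors, n >= 10, both non-constant.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed (default 1).
#' @return A one-row tibble: `r`, `ci_low`, `ci_high`, `significant`,
#'   `n_years`, `n_boot`, `seed`.
#' @export
bootstrap_pearson <- function(x, y, n_boot = 1000L, conf = 0.95, seed = 1L) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 10L) abort("Need at least 10 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in `x` or `y`.")
  r <- cor(x, y)
  rb <- local_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    boot_cor(x, y, idx)
  })
  rb <- rb[is.finite(rb)]
  a <- (1 - conf) / 2
  ci <- quantile(rb, c(a, 1 - a), names = FALSE, type = 7)
  tibble(
    r = r, ci_low = ci[1], ci_high = ci[2],
    significant = ci[1] > 0 || ci[2] < 0,
    n_years = n, n_boot = as.integer(n_boot), seed = as.integer(seed)
  )
}

# column-wise Pearson r of x[idx], y[idx] without loops
boot_cor <- function(x, y, idx) {
  n <- nrow(idx)
  X <- matrix(x[idx], nrow = n)
  Y <- matrix(y[idx], nrow = n)
  mx <- colMeans(X); my <- colMeans(Y)
  sxy <- colMeans(X * Y) - mx * my
  sxx <- colMeans(X * X) - mx^2
  syy <- colMeans(Y * Y) - my^2
  sxy / sqrt(sxx * syy)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Climate-growth correlation function
#'
#' Runs [bootstrap_pearson()] for every column of the design matrix built
#' by [build_design_matrix()]. Each column gets its own deterministic
#' sub-seed (`seed` + column position) so the whole table is reproducible
#' and individual cells can be recomputed in isolation.
#'
#' @inheritParams build_design_matrix
#' @inheritParams bootstrap_pearson
#' @param significant_only Keep only cells whose CI excludes zero
#'   (default `FALSE`).
#' @return A tibble of class `corfun`: `variable`, `window`, `r`,
#'   `ci_low`, `ci_high`, `significant`, `n_years`, with attributes
#'   `species`, `n_boot`, `seed`.
#' @export
correlation_function <- function(gic, indices, n_boot = 1000L, conf = 0.95,
                                 seed = 1L, prev_months = 9:12,
                                 cur_months = 1:9, seasonal = TRUE,
                                 significant_only = FALSE) {
  dm <- build_design_matrix(gic, indices, prev_months, cur_months, seasonal)
  cols <- names(dm)[-(1:2)]
  res <- purrr::map2(cols, seq_along(cols), function(cl, i) {
    parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
    bootstrap_pearson(
      dm[[cl]], dm$gic,
      n_boot = n_boot, conf = conf, seed = seed + i
    ) %>%
      mutate(variable = parts[1], window = parts[2], .before = 1)
  }) %>% bind_rows()
  if (significant_only) res <- filter(res, .data$significant)
  structure(
    res %>% select(-"seed", -"n_boot"),
    species = attr(gic, "species"),
    n_boot = as.integer(n_boot), seed = as.integer(seed),
    class = c("corfun", class(res))
  )
}

#' @export
glance.corfun <- function(x, ...) {
  tibble(
    species = attr(x, "species") %||% NA_character_,
    n_cells = nrow(x),
    n_significant = sum(x$significant),
    n_boot = attr(x, "n_boot"),
    seed = attr(x, "seed")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
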