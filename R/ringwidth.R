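# Per-core ring-width series -> per-tree mean series (RGS) -> species-level
# raw chronologies (RGC). Widths are stored in mm throughout; RWL files carry
# them as 0.01 mm integers (see read_rwl).

#' Average the cores of each tree into a mean radial growth series
#'
#' Each tree is usually sampled with two increment cores; their ring-width
#' series are arithmetically averaged, year by year, into a single mean
#' radial growth series (RGS) per tree. In years where only one core has a
#' measurable ring the mean is taken over the cores present (a missing ring
#' in one core is treated as absent, not as zero).
#'
#' @param cores A data frame with columns `tree_id`, `core_id`, `species`,
#'   `year`, `width_mm`. Rows with `NA` width are ignored.
#' @param warn_single Warn when a tree contributes only one core
#'   (default `TRUE`). Single-core trees are accepted.
#' @return A tibble with columns `tree_id`, `species`, `year`, `width_mm`,
#'   one row per tree-year, sorted oldest to newest within tree.
#' @examples
#' cores <- tibble::tibble(
#'   tree_id = "T1", core_id = c("A", "B"), species = "P. abies",
#'   year = 2000, width_mm = c(2, 4)
#' )
#' average_cores(cores)
#' @export
average_cores <- function(cores, warn_single = TRUE) {
  cores <- check_core_table(cores)
  if (nrow(cores) == 0L) {
    abort("`cores` contains no measurable rings.")
  }
  sp <- cores %>%
    distinct(.data$tree_id, .data$species)
  if (anyDuplicated(sp$tree_id)) {
    abort("A `tree_id` is associated with more than one species.")
  }
  n_cores <- cores %>%
    group_by(.data$tree_id) %>%
    summarise(k = n_distinct(.data$core_id), .groups = "drop")
  if (warn_single && any(n_cores$k < 2L)) {
    warn(sprintf(
      "%d tree(s) have a single core; their RGS equals that core.",
      sum(n_cores$k < 2L)
    ))
  }
  cores %>%
    group_by(.data$tree_id, .data$species, .data$year) %>%
    summarise(width_mm = mean(.data$width_mm), .groups = "drop") %>%
    arrange(.data$tree_id, .data$year)
}

#' Build a species raw radial growth chronology (RGC)
#'
#' Arithmetic mean of the per-tree series for each year, keeping only years
#' with at least `min_depth` contributing trees.
#'
#' @param trees A data frame of per-tree series (`tree_id`, `species`,
#'   `year`, `width_mm`), one species.
#' @param min_depth Minimum number of trees a year must have to be retained
#'   (default 2).
#' @return A tibble `year`, `width_mm`, `depth` of class `rgc`, with the
#'   species and the lag-1 autocorrelation of the chronology attached as
#'   attributes (summarised by `glance()`).
#' @export
build_rgc <- function(trees, min_depth = 2) {
  trees <- check_tree_table(trees)
  species <- unique(trees$species)
  if (length(species) != 1L) {
    abort("`build_rgc()` expects trees of a single species.")
  }
  chron <- trees %>%
    group_by(.data$year) %>%
    summarise(
      width_mm = mean(.data$width_mm),
      depth = dplyr::n(),
      .groups = "drop"
    ) %>%
    filter(.data$depth >= min_depth) %>%
    arrange(.data$year)
  if (nrow(chron) == 0L) {
    abort(sprintf("No year reaches the minimum sample depth of %d.", min_depth))
  }
  ar1 <- if (nrow(chron) >= 3 && sd(chron$width_mm) > 0) {
    lag1_autocorrelation(chron$width_mm)
  } else {
    NA_real_
  }
  new_rgc(chron, species = species, ar1 = ar1, n_trees = n_distinct(trees$tree_id))
}

new_rgc <- function(tbl, species, ar1, n_trees) {
  structure(tbl,
    species = species, ar1 = ar1, n_trees = n_trees,
    class = c("rgc", class(tbl))
  )
}

#' Lag-1 autocorrelation (Ar1)
#'
#' Biased autocovariance-ratio estimator
#' \deqn{r_1 = \sum_{t=2}^{n} (x_t - \bar x)(x_{t-1} - \bar x) \big/
#'   \sum_{t=1}^{n} (x_t - \bar x)^2,}
#' the magnitude of the previous year's influence on current growth.
#'
#' @param x Numeric series, length at least 3, non-constant.
#' @return A value in \[-1, 1\].
#' @examples
#' lag1_autocorrelation(1:5) # 0.4
#' @export
lag1_autocorrelation <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) abort("`x` must not contain missing values.")
  n <- length(x)
  if (n < 3L) abort("`x` must have length >= 3.")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) abort("zero variance: `x` is constant.")
  sum(xc[-1] * xc[-n]) / denom
}

#' @export
glance.rgc <- function(x, ...) {
  tibble(
    species = attr(x, "species"),
    n_trees = attr(x, "n_trees"),
    first_year = min(x$year),
    last_year = max(x$year),
    mean_width_mm = mean(x$width_mm),
    ar1 = attr(x, "ar1")
  )
}

#' @export
tidy.rgc <- function(x, ...) {
  as_tibble(unclass(x)[c("year", "width_mm", "depth")])
}

# ---- input checks ----------------------------------------------------------

check_core_table <- function(cores) {
  need <- c("tree_id", "core_id", "species", "year", "width_mm")
  miss <- setdiff(need, names(cores))
  if (length(miss)) {
    abort(paste0("`cores` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  cores <- as_tibble(cores) %>% filter(!is.na(.data$width_mm))
  if (any(cores$width_mm < 0)) abort("Ring widths must be >= 0.")
  if (anyDuplicated(cores[c("tree_id", "core_id", "year")])) {
    abort("Duplicate (tree_id, core_id, year) measurements.")
  }
  cores
}

check_tree_table <- function(trees) {
  need <- c("tree_id", "species", "year", "width_mm")
  miss <- setdiff(need, names(trees))
  if (length(miss)) {
    abort(paste0("`trees` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  trees <- as_tibble(trees) %>% filter(!is.na(.data$width_mm))
  if (nrow(trees) == 0L) abort("`trees` contains no data.")
  trees
}
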