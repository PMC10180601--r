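# Lloret resistance / recovery / resilience indices around climatic stress
# events, computed per tree on raw ring widths, plus the species-level
# medians and non-parametric group comparisons.

#' Per-tree resistance, recovery and resilience around stress events
#'
#' For a stress event in year `e` with window width `w`:
#' resistance `Rs = RG_e / mean(RG_{e-w..e-1})` (growth depression in the
#' event year relative to the pre-event level), recovery
#' `Rc = mean(RG_{e+1..e+w}) / RG_e`, resilience
#' `Rl = mean(RG_{e+1..e+w}) / mean(RG_{e-w..e-1})`; by construction
#' `Rl = Rs * Rc`. With `w = 2` the pre/post means balance out single
#' favourable or unfavourable years. Indices are ratios of raw per-tree
#' ring widths (not detrended indices); set `use = "index"` for a
#' sensitivity variant on detrended indices supplied in a `index` column.
#'
#' Tree-event combinations whose pre/post window is incomplete (e.g. the
#' last study year with `w = 2`) are dropped; a window overlapping an
#' adjacent event raises a warning.
#'
#' @param trees Per-tree series table (`tree_id`, `species`, `year`,
#'   `width_mm`; `index` if `use = "index"`).
#' @param events Integer vector of stress-event years.
#' @param w Window width in years, 1 or 2 (both may be given).
#' @param use `"width"` (default) or `"index"`.
#' @return A tibble: `species`, `tree_id`, `event`, `w`, `rg_pre`,
#'   `rg_se`, `rg_post`, `rs`, `rc`, `rl`.
#' @export
lloret_indices <- function(trees, events, w = c(1L, 2L), use = c("width", "index")) {
  use <- match.arg(use)
  valcol <- if (use == "width") "width_mm" else "index"
  trees <- as_tibble(trees)
  if (!valcol %in% names(trees)) {
    abort(sprintf("`trees` lacks the `%s` column.", valcol))
  }
  w <- as.integer(w)
  if (!all(w %in% c(1L, 2L))) abort("`w` must be 1 and/or 2.")
  events <- sort(as.integer(events))
  for (wi in w) {
    overlap <- events[c(diff(events) <= 2L * wi, FALSE)]
    if (wi == 2L && length(overlap)) {
      warn(sprintf(
        "w = 2 windows of event(s) %s overlap an adjacent stress event.",
        paste(overlap, collapse = ", ")
      ))
    }
  }
  # year x tree matrix; window means propagate NA so incomplete windows
  # drop out in the filter below
  wide <- trees %>%
    select("tree_id", "year", dplyr::all_of(valcol)) %>%
    tidyr::pivot_wider(names_from = "tree_id", values_from = dplyr::all_of(valcol)) %>%
    arrange(.data$year)
  yrs <- wide$year
  m <- as.matrix(wide[-1])
  sp_of <- trees %>% distinct(.data$tree_id, .data$species)
  window_mean <- function(window_years) {
    rows <- match(window_years, yrs)
    if (anyNA(rows)) return(rep(NA_real_, ncol(m)))
    colMeans(m[rows, , drop = FALSE])
  }
  out <- purrr::map(w, function(wi) {
    purrr::map(events, function(e) {
      tibble(
        tree_id = colnames(m), event = e, w = wi,
        rg_pre = unname(window_mean(seq(e - wi, e - 1))),
        rg_se = as.numeric(m[match(e, yrs), ]),
        rg_post = unname(window_mean(seq(e + 1, e + wi)))
      )
    }) %>% bind_rows()
  }) %>%
    bind_rows() %>%
    left_join(sp_of, by = "tree_id") %>%
    filter(
      is.finite(.data$rg_pre), is.finite(.data$rg_se),
      is.finite(.data$rg_post)
    )
  if (any(out$rg_pre <= 0 | out$rg_se <= 0)) {
    abort("Zero growth in a ratio denominator (rg_pre or rg_se).")
  }
  out %>%
    mutate(
      rs = .data$rg_se / .data$rg_pre,
      rc = .data$rg_post / .data$rg_se,
      rl = .data$rg_post / .data$rg_pre
    ) %>%
    select(
      "species", "tree_id", "event", "w",
      "rg_pre", "rg_se", "rg_post", "rs", "rc", "rl"
    ) %>%
    arrange(.data$species, .data$tree_id, .data$event, .data$w)
}

#' Species medians of the response indices
#'
#' Event-level species medians of Rs/Rc/Rl across trees, plus an `"avg"`
#' row per species/index/window aggregating across events. Two averaging
#' conventions are in circulation and both are implemented: `"pooled"`
#' (default) takes the median over all per-tree-per-event values,
#' `"of_medians"` the median of the per-event medians.
#'
#' @param indices Output of [lloret_indices()].
#' @param avg `"pooled"` or `"of_medians"`.
#' @return A tibble `species`, `index` (rs/rc/rl), `w`, `event`
#'   (a year, or `"avg"`), `value`, `n_trees`.
#' @export
species_summary <- function(indices, avg = c("pooled", "of_medians")) {
  avg <- match.arg(avg)
  long <- indices %>%
    tidyr::pivot_longer(c("rs", "rc", "rl"),
      names_to = "index", values_to = "value"
    )
  per_event <- long %>%
    group_by(.data$species, .data$index, .data$w, .data$event) %>%
    summarise(value = median(.data$value), n_trees = n(), .groups = "drop") %>%
    mutate(event = as.character(.data$event))
  averages <- if (avg == "pooled") {
    long %>%
      group_by(.data$species, .data$index, .data$w) %>%
      summarise(value = median(.data$value), n_trees = n_distinct(.data$tree_id),
        .groups = "drop"
      )
  } else {
    per_event %>%
      group_by(.data$species, .data$index, .data$w) %>%
      summarise(value = median(.data$value), n_trees = NA_integer_,
        .groups = "drop"
      )
  }
  bind_rows(per_event, mutate(averages, event = "avg")) %>%
    arrange(.data$index, .data$w, .data$species, .data$event)
}

#' Percent ring-width decline implied by a resistance value
#'
#' A resistance of Rs corresponds to a `(1 - Rs) * 100` percent decline of
#' ring width in the stress year relative to the pre-event level.
#'
#' @param rs Resistance value(s).
#' @return Percent decline.
#' @export
growth_decline_pct <- function(rs) {
  (1 - rs) * 100
}

# ---- group tests -----------------------------------------------------------

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Kruskal-Wallis rank-sum H (with tie correction, via
#' [stats::kruskal.test()]) followed by Dunn's pairwise z statistics from
#' the mean ranks,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum(t^3-t)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i}+\frac{1}{n_j}\right)}},}
#' with Holm-Sidak step-down adjusted p-values. Following the convention
#' of two-sided Dunn testing at family level alpha, a pair is rejected
#' when the adjusted p-value is at or below `alpha / 2`.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @param alpha Family significance level (default 0.05).
#' @return A list of class `kruskal_dunn`: `H`, `df`, `p_value`,
#'   `pairwise` (tibble: `group1`, `group2`, `z`, `p`, `p_adj`,
#'   `reject`), `alpha`. See [tidy.kruskal_dunn()].
#' @export
kruskal_dunn <- function(data, value, group, alpha = 0.05) {
  x <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) abort("Need at least two groups.")
  if (any(table(g) < 2L)) abort("Every group needs >= 2 observations.")
  if (length(unique(x)) == 1L) {
    kw <- list(statistic = c(H = 0), parameter = nlevels(g) - 1, p.value = 1)
  } else {
    kw <- kruskal.test(x, g)
  }
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  nn <- tapply(rk, g, length)
  ties <- table(x)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  vfac <- N * (N + 1) / 12 - tiecorr
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(p) {
    if (vfac <= 0) return(0) # all observations tied: no rank spread
    (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt(vfac * (1 / nn[[p[1]]] + 1 / nn[[p[2]]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- holm_sidak(p_raw)
  pw <- tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = z, p = p_raw, p_adj = p_adj,
    reject = p_adj <= alpha / 2
  )
  structure(
    list(
      H = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value, pairwise = pw, alpha = alpha,
      mean_ranks = rbar
    ),
    class = "kruskal_dunn"
  )
}

# Holm-Sidak step-down: sort ascending, p_adj_(i) = 1 - (1 - p_(i))^(m-i+1),
# enforce monotonicity with a running maximum.
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n", x$H, x$df, x$p_value
  ))
  print(x$pairwise)
  invisible(x)
}

#' @export
#' @rdname kruskal_dunn
#' @param x A `kruskal_dunn` object.
#' @param ... Unused.
tidy.kruskal_dunn <- function(x, ...) {
  x$pairwise
}

#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble(
    H = x$H, df = x$df, p_value = x$p_value,
    n_reject = sum(x$pairwise$reject), alpha = x$alpha
  )
}

#' One-way ANOVA with Tukey's HSD post-hoc test
#'
#' Standard one-way analysis of variance and Tukey honest significant
#' differences, used for stand attributes (DBH, height, mean radial
#' growth).
#'
#' @inheritParams kruskal_dunn
#' @return A list of class `anova_tukey`: `F`, `df`, `p_value`,
#'   `pairwise` (tibble `group1`, `group2`, `diff`, `p_adj`, `reject`).
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05) {
  d <- data.frame(y = data[[value]], g = factor(data[[group]]))
  fit <- aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  labs <- strsplit(rownames(tk), "-", fixed = TRUE)
  structure(
    list(
      F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
      p_value = an[1, "Pr(>F)"],
      pairwise = tibble(
        group1 = vapply(labs, `[`, "", 1),
        group2 = vapply(labs, `[`, "", 2),
        diff = tk[, "diff"], p_adj = tk[, "p adj"],
        reject = tk[, "p adj"] <= alpha
      ),
      alpha = alpha
    ),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
    x$df[1], x$df[2], x$F, x$p_value
  ))
  print(x$pairwise)
  invisible(x)
}

#' @export
glance.anova_tukey <- function(x, ...) {
  tibble(
    F = x$F, df1 = x$df[1], df2 = x$df[2], p_value = x$p_value,
    n_reject = sum(x$pairwise$reject), alpha = x$alpha
  )
}

#' @export
tidy.anova_tukey <- function(x, ...) {
  x$pairwise
}
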