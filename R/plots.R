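# Quick-look ggplot2 graphics for the main result types.

#' @export
autoplot.rgc <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$year, y = .data$width_mm)
  ) +
    ggplot2::geom_line(colour = "#2b6a99") +
    ggplot2::labs(
      title = sprintf("Raw radial growth chronology: %s", attr(object, "species")),
      x = "Year", y = "Ring width (mm)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gic <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$year, y = .data$index)
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "#2b6a99") +
    ggplot2::labs(
      title = sprintf("Growth index chronology: %s", attr(object, "species")),
      subtitle = sprintf(
        "Rbar = %.2f, EPS = %.2f", attr(object, "rbar"), attr(object, "eps")
      ),
      x = "Year", y = "Growth index"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.corfun <- function(object, significant_only = FALSE, ...) {
  d <- as_tibble(object)
  if (significant_only) d <- filter(d, .data$significant)
  wins <- c(tolower(MONTH_LABELS[9:12]), MONTH_LABELS[1:9], "VP", "PW")
  d <- mutate(d, window = factor(.data$window, levels = wins))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$window, y = .data$r,
      ymin = .data$ci_low, ymax = .data$ci_high,
      colour = .data$significant
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(size = 0.25) +
    ggplot2::facet_wrap(~variable) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey55")) +
    ggplot2::labs(
      title = sprintf(
        "Bootstrapped climate-growth correlations: %s",
        attr(object, "species") %||% ""
      ),
      x = NULL, y = "Pearson r (95% bootstrap CI)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Boxplots of per-tree response indices by species and event
#'
#' @param lloret Output of [lloret_indices()].
#' @param w Window width to display (default 1).
#' @return A ggplot.
#' @export
plot_response_indices <- function(lloret, w = 1L) {
  d <- lloret %>%
    filter(.data$w == !!w) %>%
    tidyr::pivot_longer(c("rs", "rc", "rl"),
      names_to = "index", values_to = "value"
    ) %>%
    mutate(index = factor(.data$index, levels = c("rs", "rc", "rl"),
      labels = c("Resistance", "Recovery", "Resilience")
    ))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = factor(.data$event), y = .data$value, fill = .data$species
    )
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(
      x = "Stress event", y = "Index value",
      title = sprintf("Response indices (window width %d)", w)
    ) +
    ggplot2::theme_minimal()
}
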