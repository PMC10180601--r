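# Bundled reference tables (plain CSV under inst/extdata).

#' Published species-median response indices for the Bayreuth comparison
#'
#' Reference medians of resistance (rs), recovery (rc) and resilience (rl)
#' for *Cedrus libani*, *Picea abies* and *Pinus sylvestris* at the
#' Bayreuth study site, per stress event (2003, 2012, 2015, 2018) and as
#' the published cross-event average, for window widths 1 and 2. The
#' two-year-window cells of 2018 are absent (the record ends in 2019, so
#' no two post-event years exist). Useful as a validation surface: e.g.
#' the percent ring-width declines implied by the resistance values via
#' [growth_decline_pct()].
#'
#' @return A tibble `species`, `index`, `w`, `event` (year or `"avg"`),
#'   `value`.
#' @export
reference_response_medians <- function() {
  readr::read_csv(
    system.file("extdata", "bayreuth_response_medians.csv",
      package = "ringclim", mustWork = TRUE
    ),
    show_col_types = FALSE,
    col_types = readr::cols(
      species = "c", index = "c", w = "i", event = "c", value = "d"
    )
  )
}
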