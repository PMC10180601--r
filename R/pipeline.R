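# End-to-end pipeline: cores -> per-tree series -> chronologies ->
# climate indices -> stress years -> correlation functions -> response
# indices, with every table written to disk and all tunables surfaced as
# arguments (never hard-coded literals downstream).

#' Run the full climate-growth analysis pipeline
#'
#' Executes chronology building, climate indexing, stress-year detection,
#' bootstrapped climate-growth correlation and Lloret response-index
#' analysis for a multi-species core table and a daily climate record, and
#' writes every result as CSV/JSON under `out_dir` (when given) together
#' with a log of all parameters and the seed.
#'
#' @param cores Core table (`tree_id`, `core_id`, `species`, `year`,
#'   `width_mm`), any number of species.
#' @param daily Daily climate table (see [climate_indices()]).
#' @param out_dir Output directory; `NULL` (default) skips writing.
#' @param stress_events `"auto"` (stress years from
#'   [detect_stress_years()], trimmed to years whose w-windows are fully
#'   covered by the growth record) or an integer vector of event years.
#' @param w Lloret window widths (default `c(1, 2)`). Events lacking a
#'   complete pre/post window at a given width are dropped at that width
#'   only.
#' @param cutoff_fraction,amplitude Spline calibration ([fit_spline()]).
#' @param n_boot,conf Bootstrap settings ([bootstrap_pearson()]).
#' @param alpha Significance level for the group tests.
#' @param seed Master seed; all randomness (bootstrap resampling) derives
#'   from it.
#' @param latitude,spei_calibration Passed to [climate_indices()].
#' @param min_depth Minimum sample depth for chronology years.
#' @param avg Averaging convention for [species_summary()].
#' @return (Invisibly) a list: `trees`, `rgc` and `gic` (per-species
#'   lists), `chronology_stats`, `indices`, `stress`, `events`,
#'   `correlations` (per-species `corfun`), `lloret`, `summary`,
#'   `group_tests`.
#' @export
run_pipeline <- function(cores, daily, out_dir = NULL,
                         stress_events = "auto", w = c(1L, 2L),
                         cutoff_fraction = 0.67, amplitude = 0.5,
                         n_boot = 1000L, conf = 0.95, alpha = 0.05,
                         seed = 1L, latitude = 49.93,
                         spei_calibration = NULL, min_depth = 2L,
                         avg = "pooled") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  trees <- stage("average_cores", average_cores(cores))
  species <- sort(unique(trees$species))

  rgc <- stage("build_rgc", lapply(
    setNames(species, species),
    function(sp) build_rgc(filter(trees, .data$species == sp), min_depth)
  ))
  gic <- stage("build_gic", lapply(
    setNames(species, species),
    function(sp) {
      build_gic(filter(trees, .data$species == sp),
        cutoff_fraction = cutoff_fraction, amplitude = amplitude,
        min_depth = min_depth
      )
    }
  ))
  chron_stats <- bind_rows(lapply(gic, glance)) %>%
    left_join(
      bind_rows(lapply(rgc, glance))[c("species", "ar1")] %>%
        rename(ar1_raw = "ar1"),
      by = "species"
    )

  indices <- stage("climate_indices", climate_indices(
    daily,
    latitude = latitude, spei_calibration = spei_calibration
  ))
  study_years <- sort(unique(trees$year))
  stress <- stage("detect_stress_years", detect_stress_years(
    indices,
    study_years = study_years
  ))

  events <- if (identical(stress_events, "auto")) {
    stress$year[stress$stress]
  } else {
    as.integer(stress_events)
  }
  # window completeness at w = 1 decides membership; wider windows drop
  # events per tree inside lloret_indices()
  events <- events[
    events - 1L >= min(study_years) & events + 1L <= max(study_years)
  ]

  correlations <- stage("correlation_function", lapply(
    setNames(species, species),
    function(sp) {
      correlation_function(gic[[sp]], indices,
        n_boot = n_boot, conf = conf,
        seed = seed + match(sp, species) * 1000L
      )
    }
  ))

  lloret <- stage("lloret_indices", lloret_indices(trees, events, w = w))
  summary <- species_summary(lloret, avg = avg)
  group_tests <- if (length(species) < 2L) {
    list() # nothing to compare across species
  } else stage("group_tests", {
    combos <- distinct(
      tidyr::pivot_longer(lloret, c("rs", "rc", "rl"),
        names_to = "index", values_to = "value"
      ),
      .data$index, .data$w
    )
    purrr::pmap(combos, function(index, w) {
      d <- lloret %>%
        tidyr::pivot_longer(c("rs", "rc", "rl"),
          names_to = "idx", values_to = "value"
        ) %>%
        filter(.data$idx == index, .data$w == !!w)
      list(
        index = index, w = w,
        test = kruskal_dunn(d, "value", "species", alpha = alpha)
      )
    })
  })

  result <- list(
    trees = trees, rgc = rgc, gic = gic,
    chronology_stats = chron_stats,
    indices = indices, stress = stress, events = events,
    correlations = correlations,
    lloret = lloret, summary = summary, group_tests = group_tests
  )

  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir, parameters = list(
      stress_events = stress_events, w = w,
      cutoff_fraction = cutoff_fraction, amplitude = amplitude,
      n_boot = n_boot, conf = conf, alpha = alpha, seed = seed,
      latitude = latitude, min_depth = min_depth, avg = avg,
      package_version = as.character(utils::packageVersion("ringclim"))
    ))
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir, parameters) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  for (sp in names(result$gic)) {
    tag <- gsub("[^A-Za-z0-9]+", "_", sp)
    readr::write_csv(tidy(result$rgc[[sp]]), p(sprintf("rgc_%s.csv", tag)))
    readr::write_csv(tidy(result$gic[[sp]]), p(sprintf("gic_%s.csv", tag)))
    readr::write_csv(
      as_tibble(result$correlations[[sp]]) %>%
        mutate(species = sp, .before = 1),
      p(sprintf("correlations_%s.csv", tag))
    )
  }
  readr::write_csv(result$chronology_stats, p("chronology_stats.csv"))
  readr::write_csv(result$indices, p("climate_indices.csv"))
  readr::write_csv(result$lloret, p("response_indices_trees.csv"))
  readr::write_csv(result$summary, p("response_indices_species.csv"))
  jsonlite::write_json(
    result$stress, p("stress_years.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  jsonlite::write_json(
    lapply(result$group_tests, function(gt) {
      list(
        index = gt$index, w = gt$w,
        glance = as.list(glance(gt$test)),
        pairwise = tidy(gt$test)
      )
    }),
    p("group_tests.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  jsonlite::write_json(parameters, p("run_log.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' Run the pipeline from a YAML configuration file
#'
#' The config maps directly onto [run_pipeline()] arguments plus input
#' paths: `growth` is a list of `{path, species}` RWL entries or a single
#' `{csv}` long-format file; `climate: {csv}` names the daily record;
#' remaining keys (`out_dir`, `stress_events`, `w`, `cutoff_fraction`,
#' `amplitude`, `n_boot`, `conf`, `alpha`, `seed`, `latitude`,
#' `min_depth`, `avg`) override the defaults.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return See [run_pipeline()].
#' @export
run_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cores <- if (!is.null(config$growth$csv)) {
    readr::read_csv(config$growth$csv, show_col_types = FALSE)
  } else {
    bind_rows(lapply(config$growth, function(g) {
      read_rwl(g$path, species = g$species)
    }))
  }
  daily <- readr::read_csv(config$climate$csv, show_col_types = FALSE) %>%
    mutate(date = as.Date(.data$date))
  args <- config[intersect(names(config), names(formals(run_pipeline)))]
  if (!is.null(args$stress_events) && !identical(args$stress_events, "auto")) {
    args$stress_events <- as.integer(unlist(args$stress_events))
  }
  if (!is.null(args$w)) args$w <- as.integer(unlist(args$w))
  do.call(run_pipeline, c(list(cores = cores, daily = daily), args))
}
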