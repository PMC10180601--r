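# Tucson / RWL decadal format. One line per series and decade:
#   <series id> <decade start year> <up to 10 values in 0.01 mm>
# the series ends at a 999 (or -9999) sentinel. By long-standing convention
# the series id concatenates a tree id and a trailing core letter.

#' Read ring widths from a Tucson/RWL decadal file
#'
#' Values are stored as integers in units of 0.01 mm and converted to mm;
#' `999` and `-9999` end-of-series markers are honoured. The last character
#' of each series id is taken as the core id and the rest as the tree id
#' (override with `id_split`).
#'
#' @param path Path to the RWL file.
#' @param species Species label attached to every core (RWL carries none).
#' @param id_split Function mapping a series id to `c(tree_id, core_id)`.
#' @return A tibble `tree_id`, `core_id`, `species`, `year`, `width_mm`.
#' @export
read_rwl <- function(path, species = NA_character_, id_split = NULL) {
  if (is.null(id_split)) {
    id_split <- function(id) {
      c(substr(id, 1L, nchar(id) - 1L), substr(id, nchar(id), nchar(id)))
    }
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) < 3L) {
      abort(sprintf("Malformed RWL row %d: fewer than 3 fields.", i))
    }
    id <- tok[[1]]
    decade <- suppressWarnings(as.integer(tok[[2]]))
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(decade) || anyNA(vals)) {
      abort(sprintf("Malformed RWL row %d: non-numeric year or value.", i))
    }
    stopv <- which(vals == 999 | vals == -9999)
    if (length(stopv)) vals <- vals[seq_len(stopv[[1]] - 1L)]
    if (!length(vals)) next
    out[[i]] <- tibble(
      series = id,
      year = decade + seq_along(vals) - 1L,
      width_mm = vals / 100
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) abort("RWL file contains no measurements.")
  if (anyDuplicated(res[c("series", "year")])) {
    abort("Duplicate (series, year) entries in RWL file.")
  }
  ids <- unname(vapply(res$series, id_split, character(2)))
  res %>%
    mutate(
      tree_id = ids[1, ], core_id = ids[2, ],
      species = species
    ) %>%
    select("tree_id", "core_id", "species", "year", "width_mm") %>%
    arrange(.data$tree_id, .data$core_id, .data$year)
}

#' Write ring widths to a Tucson/RWL decadal file
#'
#' Inverse of [read_rwl()]: widths are rounded to 0.01 mm, rows are decadal,
#' and each series is terminated with a `999` sentinel.
#'
#' @param cores A core table (`tree_id`, `core_id`, `year`, `width_mm`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(cores, path) {
  cores <- as_tibble(cores) %>%
    mutate(series = paste0(.data$tree_id, .data$core_id)) %>%
    arrange(.data$series, .data$year)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(cores$series)) {
    s <- cores[cores$series == id, ]
    if (any(diff(s$year) != 1L)) {
      abort(sprintf("Series %s has non-consecutive years.", id))
    }
    vals <- as.integer(round(s$width_mm * 100))
    years <- s$year
    vals <- c(vals, 999L)
    years <- c(years, max(years) + 1L)
    dec <- years %/% 10L
    for (d in unique(dec)) {
      sel <- dec == d
      writeLines(sprintf(
        "%-8s%4d%s", id, years[sel][1],
        paste0(sprintf("%6d", vals[sel]), collapse = "")
      ), con)
    }
  }
  invisible(path)
}

#' Write a chronology to CSV
#'
#' @param chron An `rgc` or `gic` object (or any year-indexed tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chronology_csv <- function(chron, path) {
  readr::write_csv(as_tibble(unclass(chron)), path)
  invisible(path)
}
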