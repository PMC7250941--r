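#' Richness totals and per-taxon species counts
#'
#' Counts distinct species, genera (first word of the accepted binomial) and
#' families per group and overall, plus species counts per family and per
#' genus with a deterministic ordering (descending count, ties alphabetical).
#'
#' @param summaries tibble from [build_species_summaries()].
#' @return a `herb_richness` object: list of tibbles `totals`
#'   (`group`, `nSpecies`, `nGenera`, `nFamilies`; group `"all"` is overall),
#'   `families` and `genera` (`taxon`, `group`, `speciesCount`).
#' @export
richness <- function(summaries) {
  stopifnot(nrow(summaries) > 0L)
  s <- summaries
  s$genus <- vapply(strsplit(s$speciesName, " ", fixed = TRUE), `[[`, "", 1L)
  totals_of <- function(x, label) {
    tibble::tibble(group = label,
                   nSpecies = dplyr::n_distinct(x$speciesName),
                   nGenera = dplyr::n_distinct(x$genus),
                   nFamilies = dplyr::n_distinct(x$family[!is.na(x$family)]))
  }
  totals <- dplyr::bind_rows(
    totals_of(s, "all"),
    dplyr::bind_rows(lapply(sort(unique(s$group)), function(g) {
      totals_of(s[s$group == g, ], g)
    }))
  )
  count_by <- function(col) {
    s |>
      dplyr::filter(!is.na(.data[[col]])) |>
      dplyr::count(.data[[col]], .data$group, name = "speciesCount") |>
      dplyr::rename(taxon = dplyr::all_of(col)) |>
      dplyr::arrange(dplyr::desc(.data$speciesCount), .data$taxon)
  }
  structure(list(totals = totals, families = count_by("family"),
                 genera = count_by("genus")),
            class = "herb_richness")
}

#' @export
print.herb_richness <- function(x, ...) {
  cat("Richness totals:\n")
  print(x$totals)
  cat("\nRichest families:\n")
  print(utils::head(x$families, 10L))
  invisible(x)
}

#' Top-k rows of a richness table
#'
#' @param x a `herb_richness`.
#' @param by `"families"` or `"genera"`.
#' @param k number of rows (default 10).
#' @param group optional group filter.
#' @return tibble of the k richest taxa, ties broken alphabetically.
#' @export
richest <- function(x, by = c("families", "genera"), k = 10L, group = NULL) {
  by <- match.arg(by)
  tab <- x[[by]]
  if (!is.null(group)) tab <- tab[tab$group == group, , drop = FALSE]
  utils::head(tab, k)
}

.composition_dims <- c("lifeForm", "vegetationClass", "origin",
                       "endemicToCountry", "temporalStatus", "threatCategory")

#' Composition of the catalogue along one dimension
#'
#' Tallies species per category of one trait dimension and expresses each as
#' a percentage of the (group-filtered) species total. The unrounded shares
#' always sum to 100; the rounded `pct` column uses half-up rounding at the
#' requested precision, since published tables mix integer and one-decimal
#' percentages.
#'
#' @param summaries tibble from [build_species_summaries()].
#' @param dimension one of `lifeForm`, `vegetationClass`, `origin`,
#'   `endemicToCountry`, `temporalStatus`, `threatCategory`.
#' @param group optional group filter (e.g. `"angiosperm"`).
#' @param digits rounding precision for `pct` (default 0).
#' @return a tibble (`category`, `n`, `share`, `pct`) of class
#'   `herb_composition`, descending by count.
#' @export
composition <- function(summaries, dimension, group = NULL, digits = 0L) {
  dimension <- match.arg(dimension, .composition_dims)
  s <- summaries
  if (!is.null(group)) s <- s[s$group %in% group, , drop = FALSE]
  stopifnot(nrow(s) > 0L)
  vals <- s[[dimension]]
  vals <- ifelse(is.na(vals), "no_info", as.character(vals))
  out <- tibble::as_tibble(table(category = vals), n = "n")
  out$n <- as.integer(out$n)
  out$share <- 100 * out$n / sum(out$n)
  # half-up rounding (round() is banker's)
  f <- 10^digits
  out$pct <- floor(out$share * f + 0.5) / f
  out <- dplyr::arrange(out, dplyr::desc(.data$n), .data$category)
  attr(out, "dimension") <- dimension
  class(out) <- c("herb_composition", class(out))
  out
}

#' Ranked per-collector record counts
#'
#' Counts retained records per normalised collector key, descending with
#' alphabetical tie order. Records with no collector are reported under the
#' distinguished `UNKNOWN` row rather than dropped.
#'
#' @param records occurrence tibble; `collectorKey` derived if absent.
#' @return tibble (`collector`, `records`).
#' @export
collector_stats <- function(records) {
  if (!"collectorKey" %in% names(records)) {
    records$collectorKey <- normalize_collector(records$recordedBy)
  }
  records |>
    dplyr::count(collector = .data$collectorKey, name = "records") |>
    dplyr::arrange(dplyr::desc(.data$records), .data$collector)
}

#' Records per collection year
#'
#' @param records occurrence tibble with `collectionYear`.
#' @return tibble (`year`, `records`), one row per observed year, ascending;
#'   the number of undated records is attached as attribute
#'   `"unknown_years"`.
#' @export
temporal_profile <- function(records) {
  known <- records[!is.na(records$collectionYear), , drop = FALSE]
  out <- known |>
    dplyr::count(year = .data$collectionYear, name = "records") |>
    dplyr::arrange(.data$year)
  attr(out, "unknown_years") <- sum(is.na(records$collectionYear))
  class(out) <- c("herb_temporal", class(out))
  out
}

#' Peak collection year
#'
#' @param profile tibble from [temporal_profile()].
#' @return the year with the most records (earliest year on ties), or `NA`
#'   for an empty series.
#' @export
peak_year <- function(profile) {
  if (nrow(profile) == 0L) return(NA_integer_)
  profile$year[which.max(profile$records)]
}
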