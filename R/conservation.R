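#' Classify a collection year as old or recent
#'
#' The cutoff defaults to 1969: records from the cutoff year or earlier are
#' `old`, later ones `recent`, undated ones `unknown`. (The half-century
#' convention leaves the cutoff year itself unassigned; treating it as old is
#' the conservative, priority-friendly reading and the cutoff is exposed as a
#' parameter.)
#'
#' @param year integer vector of collection years (`NA` allowed).
#' @param cutoff_year last year counted as old.
#' @return character vector: `old`, `recent` or `unknown`.
#' @export
record_age_class <- function(year, cutoff_year = 1969L) {
  dplyr::case_when(
    is.na(year) ~ "unknown",
    year <= cutoff_year ~ "old",
    TRUE ~ "recent"
  )
}

#' Temporal status of one species
#'
#' @param age_classes character vector of per-record age classes
#'   (from [record_age_class()]) for a single species; must be non-empty.
#' @return `has_recent` if any record is recent; `only_old` if at least one
#'   old record and none recent; `unknown` if every record is undated.
#' @export
species_temporal_status <- function(age_classes) {
  if (length(age_classes) == 0L) {
    stop("species_temporal_status needs at least one record", call. = FALSE)
  }
  if (any(age_classes == "recent")) "has_recent"
  else if (any(age_classes == "old")) "only_old"
  else "unknown"
}

#' The conservation-priority rule
#'
#' A species is flagged as a conservation priority when it is known from a
#' single retained record, that record is old (collected before the cutoff),
#' and the species is assessed CR, EN, VU or DD. A species whose only record
#' is undated is not a priority: the rule requires a dated old record.
#'
#' @param record_count integer vector of per-species retained record counts.
#' @param temporal_status character vector (`only_old`/`has_recent`/`unknown`).
#' @param threat_category character vector of red-list categories.
#' @return logical vector.
#' @export
flag_priority <- function(record_count, temporal_status, threat_category) {
  record_count == 1L &
    temporal_status == "only_old" &
    threat_category %in% c("CR", "EN", "VU", "DD")
}

#' Build the per-species catalogue rows
#'
#' Aggregates clean, resolved, annotated records into one row per accepted
#' species: retained record count, temporal status, traits and the priority
#' flag.
#'
#' @param records clean resolved records tibble (needs `acceptedName`,
#'   `group`, `collectionYear`; `acceptedFamily` if available).
#' @param traits per-species traits from [annotate_species()].
#' @param cutoff_year see [record_age_class()].
#' @return tibble, one row per species: `speciesName`, `group`, `family`,
#'   `recordCount`, `temporalStatus`, `vegetationClass`, `lifeForm`,
#'   `origin`, `endemicToCountry`, `threatCategory`, `priority`.
#' @export
build_species_summaries <- function(records, traits, cutoff_year = 1969L) {
  stopifnot(nrow(records) > 0L)
  if (!"acceptedFamily" %in% names(records)) {
    records$acceptedFamily <- NA_character_
  }
  age <- record_age_class(records$collectionYear, cutoff_year)
  base <- records |>
    dplyr::mutate(.age = age) |>
    dplyr::group_by(.data$acceptedName) |>
    dplyr::summarise(
      group = dplyr::first(.data$group),
      family = dplyr::first(.data$acceptedFamily),
      recordCount = dplyr::n(),
      temporalStatus = species_temporal_status(.data$.age),
      .groups = "drop"
    ) |>
    dplyr::rename(speciesName = "acceptedName")
  out <- dplyr::left_join(base, traits, by = "speciesName")
  if (!"threatCategory" %in% names(out)) out$threatCategory <- "NE"
  out$threatCategory <- dplyr::coalesce(out$threatCategory, "NE")
  out$priority <- flag_priority(out$recordCount, out$temporalStatus,
                                out$threatCategory)
  dplyr::arrange(out, .data$group, .data$speciesName)
}

#' Extract the priority-species table
#'
#' @param summaries tibble from [build_species_summaries()].
#' @return tibble (`group`, `family`, `speciesName`, `threatCategory`),
#'   ordered by group, family, species.
#' @export
priority_species <- function(summaries) {
  summaries |>
    dplyr::filter(.data$priority) |>
    dplyr::select("group", "family", "speciesName", "threatCategory") |>
    dplyr::arrange(.data$group, .data$family, .data$speciesName)
}
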