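#' Run the full catalogue pipeline
#'
#' Chains every stage: read (if paths are given), clean (determination,
#' locality, duplicates), resolve names against the backbone, apply the
#' optional taxonomist review, annotate traits and threat categories, and
#' build the per-species catalogue. Returns a `herb_catalogue` object with
#' [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#' methods.
#'
#' @param occurrences occurrence tibble or a file path.
#' @param backbone `herb_backbone` or a file path.
#' @param assessments assessments tibble or a file path.
#' @param gaz a [gazetteer()] or a gazetteer file path.
#' @param review optional review tibble or path (see [apply_review()]).
#' @param max_distance fuzzy-matching budget, see [match_name()].
#' @param cutoff_year old/recent cutoff, see [record_age_class()].
#' @param vegetation_map see [classify_vegetation()].
#' @param dialect a [dwc_dialect()] used when reading paths.
#' @return a `herb_catalogue`: list with `records` (final records),
#'   `catalogue` (per-species summaries), `ledger`, `queues` (locality
#'   review + unresolved names), `resolution_report`, `richness` and the
#'   parameters used.
#' @export
run_catalogue <- function(occurrences, backbone, assessments, gaz,
                          review = NULL, max_distance = 1L,
                          cutoff_year = 1969L,
                          vegetation_map = default_vegetation_map(),
                          dialect = dwc_dialect()) {
  occurrences <- if (is.character(occurrences)) {
    read_occurrences(occurrences, dialect)
  } else {
    as_occurrences(occurrences, column_map = dialect$column_map)
  }
  if (is.character(backbone)) backbone <- read_backbone(backbone)
  if (is.character(assessments)) assessments <- read_assessments(assessments)
  if (is.character(gaz)) gaz <- read_gazetteer(gaz)
  if (is.character(review)) {
    review <- readr::read_tsv(review, col_types = readr::cols(.default = "c"),
                              progress = FALSE, show_col_types = FALSE)
  }

  cleaned <- run_cleaning(occurrences, gaz)
  res <- resolve_records(cleaned$records, backbone, max_distance)
  rev <- apply_review(res$resolved, review, unresolved = res$unresolved)
  records <- rev$records
  ledger <- dplyr::bind_rows(cleaned$ledger, rev$ledger)

  traits <- suppressWarnings(annotate_species(
    unique(records$acceptedName), backbone, assessments,
    records = records, vegetation_map = vegetation_map,
    extra_traits = rev$traits
  ))
  catalogue <- build_species_summaries(records, traits, cutoff_year)

  structure(list(
    records = records,
    catalogue = catalogue,
    ledger = ledger,
    queues = list(locality = cleaned$review$locality,
                  unresolved = res$unresolved),
    resolution_report = res$report,
    richness = richness(catalogue),
    params = list(max_distance = max_distance, cutoff_year = cutoff_year)
  ), class = "herb_catalogue")
}

#' @export
print.herb_catalogue <- function(x, ...) {
  g <- glance(x)
  cat("Catalogue of", g$nSpecies, "species (", g$nFamilies, "families,",
      g$nGenera, "genera) from", g$nRecords, "retained records\n")
  cat("  native:", g$nNative, " non-native:", g$nNonNative,
      " threatened (CR/EN/VU):", g$nThreatened,
      " priority:", g$nPriority, "\n")
  cat("  review queues: locality", nrow(x$queues$locality),
      "| unresolved names", nrow(x$queues$unresolved), "\n")
  invisible(x)
}

#' Tidy a catalogue into its per-species table
#'
#' @param x a `herb_catalogue`.
#' @param ... unused.
#' @return the per-species summary tibble.
#' @export
tidy.herb_catalogue <- function(x, ...) x$catalogue

#' One-row catalogue overview
#'
#' @param x a `herb_catalogue`.
#' @param ... unused.
#' @return one-row tibble of headline totals.
#' @export
glance.herb_catalogue <- function(x, ...) {
  s <- x$catalogue
  tot <- x$richness$totals[x$richness$totals$group == "all", ]
  tibble::tibble(
    nRecords = nrow(x$records),
    nSpecies = tot$nSpecies,
    nGenera = tot$nGenera,
    nFamilies = tot$nFamilies,
    nNative = sum(s$origin == "native", na.rm = TRUE),
    nNonNative = sum(s$origin == "non_native", na.rm = TRUE),
    nEndemic = sum(s$endemicToCountry, na.rm = TRUE),
    nThreatened = sum(s$threatCategory %in% c("CR", "EN", "VU")),
    nPriority = sum(s$priority)
  )
}

#' Headline catalogue statistics
#'
#' The counting/flagging quantities a published checklist reports: totals,
#' per-group species counts, origin and endemism tallies, threatened and
#' single-record species, life-form and vegetation composition, temporal
#' split and the priority list.
#'
#' @param x a `herb_catalogue`.
#' @param group group used for the per-group breakdowns (default
#'   `"angiosperm"`).
#' @return named list of numbers and small tibbles.
#' @export
catalogue_stats <- function(x, group = "angiosperm") {
  s <- x$catalogue
  sg <- s[s$group == group, , drop = FALSE]
  list(
    n_records = nrow(x$records),
    n_species = dplyr::n_distinct(s$speciesName),
    n_genera = x$richness$totals$nGenera[x$richness$totals$group == "all"],
    n_families = x$richness$totals$nFamilies[x$richness$totals$group == "all"],
    n_native = sum(s$origin == "native", na.rm = TRUE),
    n_non_native = sum(s$origin == "non_native", na.rm = TRUE),
    n_species_in_group = nrow(sg),
    n_threatened_in_group = sum(sg$threatCategory %in% c("CR", "EN", "VU")),
    n_single_record_in_group = sum(sg$recordCount == 1L),
    n_herbs_in_group = sum(sg$lifeForm == "herb", na.rm = TRUE),
    n_forest_only_in_group = sum(sg$vegetationClass == "forest", na.rm = TRUE),
    n_endemic_in_group = sum(sg$endemicToCountry, na.rm = TRUE),
    n_priority = sum(s$priority),
    priority = priority_species(s)
  )
}

#' @rdname autoplot.herb_catalogue
#' @export
autoplot.herb_richness <- function(object, by = "families", k = 10L, ...) {
  top <- richest(object, by = by, k = k)
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$taxon, .data$speciesCount),
    y = .data$speciesCount, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "species", title = paste("Richest", by)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.herb_catalogue
#' @export
autoplot.herb_composition <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$category, .data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "#2a7f62") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct, "%")),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "species",
                  title = paste("Composition by", attr(object, "dimension"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.herb_catalogue
#' @export
autoplot.herb_temporal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$records)) +
    ggplot2::geom_line(colour = "#2a7f62") +
    ggplot2::labs(x = "collection year", y = "records") +
    ggplot2::theme_minimal()
}

#' Plot catalogue results
#'
#' `autoplot(catalogue, type = ...)` draws the cleaning ledger flow
#' (`"ledger"`), the temporal collection profile (`"temporal"`) or a trait
#' composition (`"composition"`, with `dimension`). Richness, composition
#' and temporal-profile tables have their own `autoplot` methods.
#'
#' @param object the object to plot.
#' @param type which catalogue view to draw.
#' @param dimension composition dimension (see [composition()]).
#' @param by,k top-k selector for richness plots.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.herb_catalogue <- function(object,
                                    type = c("ledger", "temporal",
                                             "composition"),
                                    dimension = "lifeForm", ...) {
  type <- match.arg(type)
  if (type == "temporal") {
    return(autoplot.herb_temporal(temporal_profile(object$records)))
  }
  if (type == "composition") {
    return(autoplot.herb_composition(composition(object$catalogue, dimension)))
  }
  led <- object$ledger |>
    tidyr::pivot_longer(c("kept", "removed"), names_to = "fate",
                        values_to = "n") |>
    dplyr::mutate(stage = factor(.data$stage, levels = unique(.data$stage)))
  ggplot2::ggplot(led, ggplot2::aes(x = .data$stage, y = .data$n,
                                    fill = .data$fate)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(kept = "#2a7f62",
                                          removed = "#b5443c")) +
    ggplot2::labs(x = NULL, y = "records") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
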