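#' Gazetteer of locality terms
#'
#' Locality screening is text-based (the source records rarely carry usable
#' coordinates): a gazetteer lists substrings asserting that a record lies
#' inside the target area (`include`) and substrings asserting it lies outside
#' (`exclude`). Matching is case- and accent-insensitive.
#'
#' @param include character vector of inside-area substrings.
#' @param exclude character vector of outside-area substrings.
#' @param default_policy what to do with records matching neither list:
#'   `"keep_and_queue"` keeps them but exports them for manual review;
#'   `"drop"` removes them.
#' @return a `herb_gazetteer` object.
#' @export
gazetteer <- function(include, exclude = character(),
                      default_policy = c("keep_and_queue", "drop")) {
  default_policy <- match.arg(default_policy)
  include <- unique(fold_text(include))
  exclude <- unique(fold_text(exclude))
  overlap <- intersect(include, exclude)
  if (length(overlap)) {
    stop("terms listed as both include and exclude: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(list(include = include, exclude = exclude,
                 default_policy = default_policy),
            class = "herb_gazetteer")
}

#' Read a gazetteer file
#'
#' @param path two-column TSV (`term`, `role` with role `include`/`exclude`).
#' @param default_policy see [gazetteer()].
#' @return a `herb_gazetteer`.
#' @export
read_gazetteer <- function(path, default_policy = "keep_and_queue") {
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                         show_col_types = FALSE)
  gazetteer(include = tab$term[tab$role == "include"],
            exclude = tab$term[tab$role == "exclude"],
            default_policy = default_policy)
}

.species_level_ranks <- c("SPECIES", "SUBSPECIES", "VARIETY", "FORM")
.higher_ranks <- c("FAMILY", "GENUS", "KINGDOM", "ORDER", "CLASS", "PHYLUM")

#' Keep records determined at species level
#'
#' Records determined only to family or genus, or lacking a specific epithet,
#' are removed. Infraspecific determinations (subspecies, varieties, forms)
#' are retained but collapsed to their binomial in the added
#' `speciesBinomial` column, which all species-level logic downstream uses;
#' the catalogue does not track infraspecific taxa. Unrecognised rank strings
#' are treated as undetermined and counted separately.
#'
#' @param records occurrence tibble (needs `taxonRank`, `specificEpithet`,
#'   `scientificName`).
#' @return list with tibbles `kept` (with `speciesBinomial` added) and
#'   `removed` (with a `removalReason` column: `undetermined` or
#'   `indeterminable_rank`).
#' @export
filter_determined <- function(records) {
  rank <- toupper(dplyr::coalesce(records$taxonRank, ""))
  epithet <- dplyr::coalesce(records$specificEpithet, "")
  known <- rank %in% c(.species_level_ranks, .higher_ranks, "")
  species_level <- epithet != "" & (rank %in% .species_level_ranks | rank == "")
  keep <- species_level & known
  reason <- ifelse(!known, "indeterminable_rank", "undetermined")

  kept <- records[keep, , drop = FALSE]
  kept$speciesBinomial <- collapse_binomial(kept$scientificName)
  # fall back on genus + epithet when the verbatim name lacks the epithet
  no_bi <- !grepl(" ", kept$speciesBinomial) &
    !is.na(kept$genus) & kept$genus != ""
  kept$speciesBinomial[no_bi] <-
    paste(kept$genus[no_bi], kept$specificEpithet[no_bi])

  removed <- records[!keep, , drop = FALSE]
  removed$removalReason <- reason[!keep]
  list(kept = kept, removed = removed)
}

# per-record gazetteer decision: kept / removed / queued
.locality_decision <- function(locality, gaz) {
  loc <- fold_text(dplyr::coalesce(locality, ""))
  any_match <- function(terms, boundary = FALSE) {
    if (length(terms) == 0L) return(rep(FALSE, length(loc)))
    pats <- vapply(terms, function(t) {
      esc <- stringr::str_escape(t)
      if (boundary) paste0("(^|[^[:alnum:]])", esc, "([^[:alnum:]]|$)") else esc
    }, character(1))
    Reduce(`|`, lapply(pats, function(p) stringr::str_detect(loc, p)))
  }
  inc_sub <- any_match(gaz$include)
  inc_bound <- any_match(gaz$include, boundary = TRUE)
  exc <- any_match(gaz$exclude)

  dplyr::case_when(
    exc & inc_bound ~ "kept",          # whole-word inside-area evidence wins
    exc & inc_sub ~ "queued",          # conflicting partial evidence
    exc ~ "removed",
    inc_sub ~ "kept",
    gaz$default_policy == "drop" ~ "removed",
    TRUE ~ "queued"                    # keep_and_queue: kept but reviewed
  )
}

#' Remove records whose locality lies outside the target area
#'
#' A record is removed when an exclude term matches and no include term
#' matches. An include term matching on a whole-word boundary overrides an
#' exclude match (the record is kept); an include term matching only as a
#' partial substring of an excluded place name is ambiguous and the record is
#' queued for manual review instead of being dropped. Records matching
#' neither list follow the gazetteer's default policy; under
#' `keep_and_queue` they are kept in the pipeline and exported for review,
#' mirroring the manual pass a text-only filter always needs.
#'
#' @param records occurrence tibble with a `locality` column.
#' @param gaz a [gazetteer()].
#' @return list of tibbles `kept`, `removed`, `queued` (queued is a subset of
#'   kept, annotated with `reviewReason`).
#' @export
filter_locality <- function(records, gaz) {
  stopifnot(inherits(gaz, "herb_gazetteer"))
  if (nrow(records) == 0L) {
    return(list(kept = records, removed = records, queued = records))
  }
  decision <- .locality_decision(records$locality, gaz)
  kept <- records[decision != "removed", , drop = FALSE]
  removed <- records[decision == "removed", , drop = FALSE]
  queued <- records[decision == "queued", , drop = FALSE]
  if (nrow(queued)) queued$reviewReason <- "locality_unconfirmed"
  list(kept = kept, removed = removed, queued = queued)
}

#' Remove herbarium duplicates on the collector/number/year key
#'
#' Sheets from the same gathering share collector, collector number and
#' collection year. Among records whose key is complete (collector known,
#' number present, year present), exactly one representative per key is
#' retained: the one with the lexicographically smallest `catalogNumber`,
#' which makes the choice deterministic and order-free. Records with any key
#' component missing are never merged. Duplicates across different
#' collections (herbaria) do merge.
#'
#' @param records occurrence tibble; a `collectorKey` column is derived with
#'   [normalize_collector()] if absent.
#' @return list with `unique` (retained records), `removed`, and `pairs`, a
#'   tibble of (`kept`, `removed`) catalogue numbers.
#' @export
deduplicate <- function(records) {
  if (!"collectorKey" %in% names(records)) {
    records$collectorKey <- normalize_collector(records$recordedBy)
  }
  if (nrow(records) == 0L) {
    return(list(unique = records, removed = records,
                pairs = tibble::tibble(kept = character(), removed = character())))
  }
  num <- dplyr::coalesce(records$recordNumber, "")
  complete <- records$collectorKey != "UNKNOWN" & num != "" &
    !is.na(records$collectionYear)
  key <- ifelse(complete,
                paste(records$collectorKey, num, records$collectionYear,
                      sep = "\r"),
                NA_character_)
  ord <- order(key, records$catalogNumber, na.last = TRUE)
  first_of_key <- !duplicated(key[ord], incomparables = NA)
  keep <- logical(nrow(records))
  keep[ord] <- first_of_key
  keep[!complete] <- TRUE

  removed <- records[!keep, , drop = FALSE]
  uniq <- records[keep, , drop = FALSE]
  if (nrow(removed)) {
    reps <- uniq[!is.na(key[keep]), c("catalogNumber")]
    reps$key <- key[keep][!is.na(key[keep])]
    pairs <- tibble::tibble(key = key[!keep], removed = removed$catalogNumber)
    pairs <- dplyr::left_join(pairs, reps, by = "key")
    pairs <- tibble::tibble(kept = pairs$catalogNumber, removed = pairs$removed)
  } else {
    pairs <- tibble::tibble(kept = character(), removed = character())
  }
  list(unique = uniq, removed = removed, pairs = pairs)
}

.ledger_row <- function(group, stage, input, kept, removed, delta = 0L,
                        reason = "") {
  tibble::tibble(group = group, stage = stage, input = as.integer(input),
                 kept = as.integer(kept), removed = as.integer(removed),
                 delta = as.integer(delta), reason = reason)
}

#' Validate ledger accounting
#'
#' Checks, per group, that every stage conserves records
#' (`input == kept + removed`) and that consecutive stages chain
#' (`kept + delta` of one stage equals `input` of the next).
#'
#' @param ledger a ledger tibble.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_ledger <- function(ledger) {
  bad <- ledger$input != ledger$kept + ledger$removed
  if (any(bad)) {
    stop("ledger stage does not conserve records: ",
         paste(ledger$stage[bad], collapse = ", "), call. = FALSE)
  }
  for (g in unique(ledger$group)) {
    sub <- ledger[ledger$group == g, ]
    if (nrow(sub) > 1L) {
      carried <- sub$kept[-nrow(sub)] + sub$delta[-nrow(sub)]
      if (any(carried != sub$input[-1L])) {
        stop("ledger stages do not chain for group ", g, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Replay a ledger from printed stage counts
#'
#' Builds a ledger for one group from an input total and a named vector of
#' per-stage removal counts, in order. Useful to check that published
#' flow-diagram counts telescope.
#'
#' @param group group label.
#' @param input starting record count.
#' @param removed named integer vector, stage name -> records removed.
#' @return a ledger tibble; the final `kept` is `input - sum(removed)`.
#' @examples
#' ledger_replay("angiosperm", 10888,
#'               c(locality = 95, duplicates = 734))
#' @export
ledger_replay <- function(group, input, removed) {
  stopifnot(!is.null(names(removed)))
  rows <- vector("list", length(removed))
  cur <- as.integer(input)
  for (i in seq_along(removed)) {
    r <- as.integer(removed[[i]])
    rows[[i]] <- .ledger_row(group, names(removed)[i], cur, cur - r, r)
    cur <- cur - r
  }
  out <- dplyr::bind_rows(rows)
  validate_ledger(out)
  out
}

#' Final retained count of a ledger
#'
#' @param ledger a ledger tibble.
#' @return named integer vector: final `kept + delta` per group.
#' @export
ledger_final <- function(ledger) {
  out <- vapply(split(ledger, ledger$group), function(sub) {
    as.integer(sub$kept[nrow(sub)] + sub$delta[nrow(sub)])
  }, integer(1))
  out[unique(ledger$group)]
}

#' Run the cleaning protocol
#'
#' Applies the three cleaning stages in their fixed order — species-level
#' determination, locality screening, duplicate removal — separately within
#' each record group, accumulating a per-(group, stage) ledger and the
#' locality review queue.
#'
#' @param records occurrence tibble from [read_occurrences()].
#' @param gaz a [gazetteer()].
#' @return list with `records` (clean tibble, `speciesBinomial` and
#'   `collectorKey` added), `ledger`, `review` (list with `locality` queue
#'   and `removed` records per stage) and `pairs` (dedup pairs).
#' @export
run_cleaning <- function(records, gaz) {
  groups <- if (nrow(records)) unique(records$group) else "unknown"
  ledger <- list(); clean <- list(); queued <- list(); pairs <- list()
  removed <- list(determination = list(), locality = list(), duplicates = list())
  for (g in groups) {
    sub <- records[records$group == g, , drop = FALSE]
    n0 <- nrow(sub)

    det <- filter_determined(sub)
    n_ind <- if (nrow(det$removed)) {
      sum(det$removed$removalReason == "indeterminable_rank")
    } else 0L
    reason <- "not determined to species level"
    if (n_ind > 0L) {
      reason <- paste0(reason, " (", n_ind, " with indeterminable rank)")
    }
    ledger[[length(ledger) + 1L]] <-
      .ledger_row(g, "determination", n0, nrow(det$kept), nrow(det$removed),
                  reason = reason)

    loc <- filter_locality(det$kept, gaz)
    ledger[[length(ledger) + 1L]] <-
      .ledger_row(g, "locality", nrow(det$kept), nrow(loc$kept),
                  nrow(loc$removed), reason = "locality outside target area")

    loc$kept$collectorKey <- normalize_collector(loc$kept$recordedBy)
    dd <- deduplicate(loc$kept)
    ledger[[length(ledger) + 1L]] <-
      .ledger_row(g, "duplicates", nrow(loc$kept), nrow(dd$unique),
                  nrow(dd$removed),
                  reason = "duplicate collector/number/year key")

    clean[[g]] <- dd$unique
    queued[[g]] <- loc$queued
    pairs[[g]] <- dd$pairs
    removed$determination[[g]] <- det$removed
    removed$locality[[g]] <- loc$removed
    removed$duplicates[[g]] <- dd$removed
  }
  ledger <- dplyr::bind_rows(ledger)
  validate_ledger(ledger)
  list(
    records = dplyr::bind_rows(clean),
    ledger = ledger,
    review = list(locality = dplyr::bind_rows(queued),
                  removed = lapply(removed, dplyr::bind_rows)),
    pairs = dplyr::bind_rows(pairs)
  )
}
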