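.fold_name <- function(x) {
  fold_text(stringr::str_remove_all(as.character(x), "[×x](?=[[:upper:]])|×"))
}

.split_binomial <- function(x) {
  parts <- stringr::str_split_fixed(stringr::str_squish(x), "\\s+", 2L)
  list(genus = parts[, 1L], epithet = parts[, 2L])
}

# backbone lookup structures shared by match_name / resolve_records
.backbone_index <- function(backbone) {
  folded <- .fold_name(backbone$name)
  sp <- .split_binomial(folded)
  list(folded = folded, genus = sp$genus, epithet = sp$epithet,
       status = backbone$status, accepted = backbone$acceptedName,
       name = backbone$name)
}

.match_one <- function(query, idx, max_distance) {
  qf <- .fold_name(query)
  if (is.na(qf) || qf == "") stop("empty query name", call. = FALSE)
  none <- tibble::tibble(query = query, matchType = "none",
                         acceptedName = NA_character_,
                         editDistance = NA_integer_,
                         candidates = list(character()))

  hit <- which(idx$folded == qf)
  if (length(hit)) {
    # exact accepted preferred over exact synonym
    acc <- hit[idx$status[hit] == "accepted"]
    h <- if (length(acc)) acc[[1L]] else hit[[1L]]
    return(tibble::tibble(
      query = query,
      matchType = if (idx$status[h] == "accepted") "exact_accepted" else "synonym",
      acceptedName = idx$accepted[h], editDistance = 0L,
      candidates = list(character())
    ))
  }
  if (max_distance <= 0L) return(none)

  q <- .split_binomial(qf)
  dg <- utils::adist(q$genus, idx$genus)[1L, ]
  de <- utils::adist(q$epithet, idx$epithet)[1L, ]
  d <- dg + de
  if (min(d) > max_distance) return(none)
  near <- which(d == min(d))
  accepted_set <- unique(idx$accepted[near])
  if (length(accepted_set) > 1L) {
    return(tibble::tibble(query = query, matchType = "ambiguous",
                          acceptedName = NA_character_,
                          editDistance = as.integer(min(d)),
                          candidates = list(sort(idx$name[near]))))
  }
  any_accepted <- any(idx$status[near] == "accepted")
  tibble::tibble(
    query = query,
    matchType = if (any_accepted) "fuzzy_accepted" else "fuzzy_synonym",
    acceptedName = accepted_set, editDistance = as.integer(min(d)),
    candidates = list(character())
  )
}

#' Match one binomial against the backbone
#'
#' Resolution prefers, in order: an exact match to an accepted name; an exact
#' match to a synonym (resolved to its accepted name); a fuzzy match within
#' `max_distance` total edits, where genus and epithet Levenshtein distances
#' are summed. Matching is case- and accent-insensitive and ignores hybrid
#' markers. When several equally-near fuzzy candidates resolve to different
#' accepted names the match is `ambiguous` and the candidates are listed;
#' ties are never auto-broken. Candidates that are merely different entry
#' points to the same accepted name (a synonym and its accepted name, both
#' one edit away) are not a tie.
#'
#' @param query a binomial (genus + specific epithet).
#' @param backbone a `herb_backbone` from [read_backbone()]/[as_backbone()].
#' @param max_distance maximum summed edit distance for fuzzy matching
#'   (default 1; 0 disables fuzzy search, leaving a pure dictionary lookup).
#' @return one-row tibble: `query`, `matchType` (`exact_accepted`, `synonym`,
#'   `fuzzy_accepted`, `fuzzy_synonym`, `ambiguous`, `none`), `acceptedName`,
#'   `editDistance`, `candidates` (list-column).
#' @export
match_name <- function(query, backbone, max_distance = 1L) {
  stopifnot(length(query) == 1L)
  .match_one(query, .backbone_index(backbone), as.integer(max_distance))
}

#' Resolve cleaned records against the backbone
#'
#' Each record's species binomial is matched with [match_name()] semantics;
#' resolved records gain `acceptedName`, `matchType`, `editDistance`, and the
#' backbone's `group` and family for the accepted name (`acceptedFamily`).
#' Records whose name matches nothing, or matches ambiguously, go to the
#' unresolved queue — the automated counterpart of sending them to a
#' taxonomist — and stay out of the catalogue until a review file re-admits
#' them. No record is lost: resolved + unresolved = input.
#'
#' @param records cleaned occurrence tibble with a `speciesBinomial` column
#'   (from [filter_determined()]; falls back to collapsing
#'   `scientificName`).
#' @param backbone a `herb_backbone`.
#' @param max_distance see [match_name()].
#' @return list with `resolved`, `unresolved` (with `matchType` and
#'   `candidates`), and `report`, a tibble of per-matchType counts.
#' @export
resolve_records <- function(records, backbone, max_distance = 1L) {
  if (!"speciesBinomial" %in% names(records)) {
    records$speciesBinomial <- collapse_binomial(records$scientificName)
  }
  if (nrow(records) == 0L) {
    return(list(resolved = records, unresolved = records,
                report = tibble::tibble(matchType = character(), n = integer())))
  }
  idx <- .backbone_index(backbone)
  queries <- unique(records$speciesBinomial)
  matches <- dplyr::bind_rows(
    lapply(queries, .match_one, idx = idx, max_distance = as.integer(max_distance))
  )
  hit <- matches[match(records$speciesBinomial, matches$query), ]
  records$acceptedName <- hit$acceptedName
  records$matchType <- hit$matchType
  records$editDistance <- hit$editDistance
  records$candidates <- hit$candidates

  ok <- !hit$matchType %in% c("none", "ambiguous")
  resolved <- records[ok, , drop = FALSE]
  unresolved <- records[!ok, , drop = FALSE]

  # higher group and family come from the accepted entry
  acc_idx <- match(resolved$acceptedName, backbone$name)
  resolved$group <- dplyr::coalesce(backbone$group[acc_idx], "unknown")
  resolved$acceptedFamily <- backbone$family[acc_idx]

  report <- dplyr::count(
    tibble::tibble(matchType = hit$matchType), .data$matchType, name = "n"
  )
  list(resolved = resolved, unresolved = unresolved, report = report)
}

#' Assign the higher group from the backbone
#'
#' @param acceptedName character vector of accepted binomials (`NA` for
#'   unresolved records).
#' @param backbone a `herb_backbone`.
#' @return character vector of groups; `"unknown"` where unresolved or absent.
#' @export
assign_group <- function(acceptedName, backbone) {
  out <- backbone$group[match(acceptedName, backbone$name)]
  dplyr::coalesce(out, "unknown")
}

#' Apply a taxonomist review file
#'
#' The review file carries expert decisions that no automated stage can make:
#' `accept_as` admits a queued (or overrides a resolved) record under a given
#' accepted name; `remove` deletes a record; `add` appends an
#' externally-documented record (e.g. a voucher from another herbarium).
#' Added rows may carry trait columns (`group`, `family`, `origin`,
#' `endemicToCountry`, `threatCategory`) supplied by the reviewer; these are
#' returned for the annotation stage. All actions are logged as signed
#' ledger entries.
#'
#' @param resolved resolved records tibble (from [resolve_records()]).
#' @param review review tibble with columns `catalogNumber`, `action`
#'   (`accept_as`/`remove`/`add`), `name`, plus optional trait columns.
#' @param unresolved the unresolved queue (searched by `accept_as`).
#' @return list with `records` (updated), `ledger` (review stage rows) and
#'   `traits` (reviewer-supplied per-species traits, possibly empty).
#' @export
apply_review <- function(resolved, review = NULL, unresolved = NULL) {
  n0 <- nrow(resolved)
  mk_rows <- function(removed_n, added_n) {
    dplyr::bind_rows(
      .ledger_row("all", "review_removals", n0, n0 - removed_n, removed_n,
                  reason = "removed by taxonomist review"),
      .ledger_row("all", "review_additions", n0 - removed_n, n0 - removed_n,
                  0L, delta = added_n,
                  reason = "added from external sources or review queue")
    )
  }
  if (is.null(review) || nrow(review) == 0L) {
    return(list(records = resolved, ledger = mk_rows(0L, 0L),
                traits = tibble::tibble()))
  }
  for (col in c("catalogNumber", "action", "name")) {
    if (!col %in% names(review)) stop("review column missing: ", col, call. = FALSE)
  }
  known <- c(resolved$catalogNumber,
             if (!is.null(unresolved)) unresolved$catalogNumber)
  not_add <- review[review$action != "add", , drop = FALSE]
  bad <- setdiff(not_add$catalogNumber, known)
  if (length(bad)) {
    stop("review action on unknown catalogNumber: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  records <- resolved
  removed_n <- 0L
  added_n <- 0L
  for (i in seq_len(nrow(review))) {
    row <- review[i, ]
    if (row$action == "accept_as") {
      in_main <- records$catalogNumber == row$catalogNumber
      if (any(in_main)) {
        records$acceptedName[in_main] <- row$name
        records$matchType[in_main] <- "review"
      } else {
        rec <- unresolved[unresolved$catalogNumber == row$catalogNumber, ,
                          drop = FALSE]
        rec$acceptedName <- row$name
        rec$matchType <- "review"
        if (!"group" %in% names(rec) || is.na(rec$group[1]) ||
            rec$group[1] == "unknown") {
          if ("group" %in% names(row) && !is.na(row$group)) {
            rec$group <- row$group
          }
        }
        records <- dplyr::bind_rows(records, rec)
        added_n <- added_n + nrow(rec)  # re-admission from the review queue
      }
    } else if (row$action == "remove") {
      hit <- records$catalogNumber == row$catalogNumber
      removed_n <- removed_n + sum(hit)
      records <- records[!hit, , drop = FALSE]
    } else if (row$action == "add") {
      rec <- tibble::tibble(
        catalogNumber = row$catalogNumber,
        scientificName = row$name,
        speciesBinomial = collapse_binomial(row$name),
        acceptedName = row$name,
        matchType = "review",
        group = if ("group" %in% names(row)) dplyr::coalesce(row$group, "unknown")
                else "unknown",
        acceptedFamily = if ("family" %in% names(row)) row$family
                         else NA_character_
      )
      for (extra in c("recordedBy", "recordNumber", "eventDate", "locality",
                      "collectionCode")) {
        if (extra %in% names(row)) rec[[extra]] <- row[[extra]]
      }
      if ("eventDate" %in% names(rec)) {
        rec$collectionYear <- parse_collection_year(rec$eventDate)
      }
      rec$collectorKey <- normalize_collector(
        if ("recordedBy" %in% names(rec)) rec$recordedBy else NA_character_
      )
      records <- dplyr::bind_rows(records, rec)
      added_n <- added_n + 1L
    } else {
      stop("unknown review action: ", row$action, call. = FALSE)
    }
  }

  trait_cols <- intersect(c("origin", "endemicToCountry", "threatCategory",
                            "lifeForm", "family", "group"), names(review))
  traits <- review[review$action %in% c("add", "accept_as"),
                   c("name", trait_cols), drop = FALSE]
  if (nrow(traits)) names(traits)[1] <- "speciesName"

  list(records = records, ledger = mk_rows(removed_n, added_n),
       traits = traits)
}
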