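#' @importFrom rlang .data
NULL

# Checklist column order. The published layout carries 19 columns; the slot
# between specificEpithet and scientificNameAuthorship holds the terminal
# infraspecific epithet.
dwc_checklist_columns <- c(
  "taxonID", "scientificName", "kingdom", "family", "genus",
  "specificEpithet", "infraspecificEpithet", "scientificNameAuthorship",
  "modified", "rightsHolder", "typeStatus", "taxonRank", "collectionCode",
  "catalogNumber", "locality", "recordedBy", "eventDate",
  "verbatimLongitude", "verbatimLatitude"
)

#' Default column map for occurrence tables
#'
#' Maps file header labels to the internal Darwin Core field names. The
#' defaults accept the 19-column checklist layout (with `EventDate` as the
#' published spelling of `eventDate`) plus the common extras found in
#' herbarium database dumps (`recordNumber`, `municipality`, `stateProvince`,
#' `group`, `lifeForm`). Supply a named character vector
#' (`c(fileLabel = "internalName", ...)`) to ingest exports with other
#' headers; it is merged over the defaults.
#'
#' @param ... named overrides, `fileLabel = "internalName"`.
#' @return named character vector mapping file labels to internal names.
#' @export
dwc_column_map <- function(...) {
  base <- stats::setNames(dwc_checklist_columns, dwc_checklist_columns)
  base <- c(base,
    EventDate     = "eventDate",
    recordNumber  = "recordNumber",
    municipality  = "municipality",
    stateProvince = "stateProvince",
    group         = "group",
    lifeForm      = "lifeForm"
  )
  dots <- c(...)
  if (length(dots)) base[names(dots)] <- dots
  base[!duplicated(names(base))]
}

#' File dialect for occurrence tables
#'
#' @param delim field delimiter; `NULL` guesses from the file extension
#'   (`.csv` is comma, anything else tab).
#' @param encoding file encoding (default UTF-8; accents are preserved on
#'   read, normalisation happens only inside matching functions).
#' @param column_map a map from [dwc_column_map()].
#' @return a `dwc_dialect` list.
#' @export
dwc_dialect <- function(delim = NULL, encoding = "UTF-8",
                        column_map = dwc_column_map()) {
  structure(list(delim = delim, encoding = encoding, column_map = column_map),
            class = "dwc_dialect")
}

.guess_delim <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_table <- function(path, dialect) {
  readr::read_delim(
    path,
    delim = .guess_delim(path, dialect$delim),
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = dialect$encoding),
    na = c("", "NA"),
    progress = FALSE, show_col_types = FALSE
  )
}

#' Read an occurrence-record table
#'
#' Reads a delimited occurrence table (Darwin Core headers by default), maps
#' columns through the dialect's column map, parses collection years from the
#' verbatim event date, validates coordinates and attaches a parse report.
#' Every input row yields exactly one record; nothing is dropped silently.
#' Unknown columns are preserved untouched.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect a [dwc_dialect()].
#' @return a tibble of occurrence records with (at least) the internal fields
#'   `catalogNumber`, `scientificName`, `taxonRank`, `specificEpithet`,
#'   `recordedBy`, `recordNumber`, `eventDate`, `collectionYear`, `locality`,
#'   `group`, `verbatimLatitude`, `verbatimLongitude`. The parse report is
#'   attached as attribute `"parse_report"` (see [parse_report()]).
#' @export
read_occurrences <- function(path, dialect = dwc_dialect()) {
  raw <- .read_table(path, dialect)
  as_occurrences(raw, column_map = dialect$column_map, source = path)
}

#' Normalise an in-memory occurrence table
#'
#' Applies the same column mapping, mandatory-column checks, year parsing and
#' coordinate validation as [read_occurrences()], for tables already in
#' memory.
#'
#' @param raw a data frame of occurrence records.
#' @param column_map see [dwc_column_map()].
#' @param source label used in error messages.
#' @return a normalised occurrence tibble with a parse report attached.
#' @export
as_occurrences <- function(raw, column_map = dwc_column_map(),
                           source = "input") {
  raw <- tibble::as_tibble(raw)
  path <- source
  cmap <- column_map
  hit <- intersect(names(raw), names(cmap))
  names(raw)[match(hit, names(raw))] <- unname(cmap[hit])

  for (col in c("catalogNumber", "scientificName")) {
    if (!col %in% names(raw)) {
      stop("mandatory column missing from ", path, ": ", col, call. = FALSE)
    }
  }
  dup <- raw$catalogNumber[duplicated(raw$catalogNumber)]
  if (length(dup)) {
    stop("duplicated catalogNumber within file: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  # guarantee the standard fields exist
  need_chr <- c("collectionCode", "family", "genus", "specificEpithet",
                "infraspecificEpithet", "taxonRank", "scientificNameAuthorship",
                "recordedBy", "recordNumber", "eventDate", "locality",
                "municipality", "stateProvince", "typeStatus", "group",
                "lifeForm")
  for (col in need_chr) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  raw$group <- ifelse(is.na(raw$group), "unknown", raw$group)

  year <- parse_collection_year(raw$eventDate)
  has_date <- !is.na(raw$eventDate) & raw$eventDate != ""
  raw$collectionYear <- year

  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  lat <- num_or_na(raw$verbatimLatitude %||% NA_character_)
  lon <- num_or_na(raw$verbatimLongitude %||% NA_character_)
  bad_coord <- sum(!is.na(lat) & abs(lat) > 90) + sum(!is.na(lon) & abs(lon) > 180)
  lat[!is.na(lat) & abs(lat) > 90] <- NA_real_
  lon[!is.na(lon) & abs(lon) > 180] <- NA_real_
  raw$verbatimLatitude <- lat
  raw$verbatimLongitude <- lon

  report <- tibble::tibble(
    rows_read = nrow(raw),
    records = nrow(raw),
    year_parsed = sum(!is.na(year)),
    year_unparseable = sum(has_date & is.na(year)),
    year_missing = sum(!has_date),
    collector_missing = sum(is.na(raw$recordedBy) | raw$recordedBy == ""),
    coordinates_out_of_range = bad_coord
  )
  attr(raw, "parse_report") <- report
  raw
}

#' Retrieve the parse report attached by [read_occurrences()]
#'
#' @param x a tibble returned by [read_occurrences()].
#' @return a one-row tibble of parse counts.
#' @export
parse_report <- function(x) attr(x, "parse_report")

#' Read a taxonomic backbone table
#'
#' The backbone emulates a national flora list: one row per name, accepted or
#' synonym, with the accepted name, higher taxonomy, origin, endemism, life
#' forms and vegetation types. Multi-valued fields (`lifeForms`,
#' `vegetationTypes`) are pipe-separated in the file and become list-columns.
#' Invariants are enforced at load time: names unique; every synonym points to
#' an accepted entry; accepted entries point to themselves.
#'
#' @param path path to a delimited file with columns `name`, `status`,
#'   `acceptedName` (others optional: `author`, `group`, `family`, `origin`,
#'   `endemicToCountry`, `lifeForms`, `vegetationTypes`).
#' @param dialect a [dwc_dialect()] (the column map is not applied).
#' @return a `herb_backbone` tibble.
#' @export
read_backbone <- function(path, dialect = dwc_dialect()) {
  raw <- .read_table(path, dialect)
  as_backbone(raw)
}

#' Validate a backbone table
#'
#' @param x a data frame with at least `name`, `status`, `acceptedName`.
#' @return a validated `herb_backbone` tibble with list-columns `lifeForms`
#'   and `vegetationTypes`.
#' @export
as_backbone <- function(x) {
  x <- tibble::as_tibble(x)
  for (col in c("name", "status", "acceptedName")) {
    if (!col %in% names(x)) stop("backbone column missing: ", col, call. = FALSE)
  }
  dup <- x$name[duplicated(x$name)]
  if (length(dup)) {
    stop("duplicate backbone name rows: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_status <- setdiff(unique(x$status), c("accepted", "synonym"))
  if (length(bad_status)) {
    stop("unknown backbone status: ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  }
  x$acceptedName <- ifelse(x$status == "accepted", x$name, x$acceptedName)
  syn <- x[x$status == "synonym", ]
  acc <- x$name[x$status == "accepted"]
  missing_acc <- setdiff(syn$acceptedName, acc)
  if (length(missing_acc)) {
    stop("synonym acceptedName not an accepted entry: ",
         paste(missing_acc, collapse = ", "), call. = FALSE)
  }
  for (col in c("author", "group", "family", "origin")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  # cultivated/naturalised entries count as non-native
  x$origin <- dplyr::case_when(
    is.na(x$origin) ~ NA_character_,
    x$origin %in% c("cultivated", "naturalised", "naturalized", "non_native") ~
      "non_native",
    TRUE ~ "native"
  )
  if (!"endemicToCountry" %in% names(x)) x$endemicToCountry <- NA
  if (is.character(x$endemicToCountry)) {
    x$endemicToCountry <- dplyr::case_when(
      tolower(x$endemicToCountry) %in% c("true", "yes", "1") ~ TRUE,
      tolower(x$endemicToCountry) %in% c("false", "no", "0") ~ FALSE,
      TRUE ~ NA
    )
  }
  split_multi <- function(col) {
    if (!col %in% names(x)) return(rep(list(character()), nrow(x)))
    if (is.list(x[[col]])) return(x[[col]])
    lapply(stringr::str_split(dplyr::coalesce(x[[col]], ""), "\\s*\\|\\s*"),
           function(v) v[v != ""])
  }
  x$lifeForms <- split_multi("lifeForms")
  x$vegetationTypes <- split_multi("vegetationTypes")
  class(x) <- c("herb_backbone", class(x))
  x
}

#' Write a backbone table
#'
#' Inverse of [read_backbone()]; list-columns are re-joined with `|`.
#'
#' @param backbone a `herb_backbone` tibble.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_backbone <- function(backbone, path) {
  out <- tibble::as_tibble(backbone)
  out$lifeForms <- vapply(out$lifeForms, paste, character(1), collapse = "|")
  out$vegetationTypes <- vapply(out$vegetationTypes, paste, character(1),
                                collapse = "|")
  out$endemicToCountry <- as.character(out$endemicToCountry)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

.threat_levels <- c("CR", "EN", "VU", "NT", "LC", "DD", "NE")

#' Read a threat-assessment table
#'
#' One row per assessed species with its red-list category. Species absent
#' from the table are treated as not evaluated (`NE`) when queried through
#' [threat_category()].
#'
#' @param path path to a delimited file with columns `speciesName`,
#'   `category`.
#' @param dialect a [dwc_dialect()].
#' @return a tibble with columns `speciesName`, `category`.
#' @export
read_assessments <- function(path, dialect = dwc_dialect()) {
  raw <- .read_table(path, dialect)
  as_assessments(raw)
}

#' Validate a threat-assessment table
#'
#' @param x a data frame with columns `speciesName`, `category`.
#' @return a validated tibble.
#' @export
as_assessments <- function(x) {
  x <- tibble::as_tibble(x)
  for (col in c("speciesName", "category")) {
    if (!col %in% names(x)) stop("assessment column missing: ", col, call. = FALSE)
  }
  bad <- setdiff(unique(x$category), .threat_levels)
  if (length(bad)) {
    stop("unknown threat category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- x$speciesName[duplicated(x$speciesName)]
  if (length(dup)) {
    stop("multiple assessments for: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  x[c("speciesName", "category")]
}

#' Look up threat categories, defaulting to NE
#'
#' @param species character vector of accepted binomials.
#' @param assessments tibble from [read_assessments()] / [as_assessments()].
#' @return character vector of categories; `"NE"` where absent.
#' @export
threat_category <- function(species, assessments) {
  idx <- match(species, assessments$speciesName)
  out <- assessments$category[idx]
  out[is.na(idx)] <- "NE"
  out
}

#' Write the catalogue checklist
#'
#' Emits the 19-column Darwin Core checklist layout, one row per retained
#' record, with empty strings for absent values. Re-reading the file with
#' [read_occurrences()] restores the field values bit-for-bit (round-trip
#' stable).
#'
#' @param records a tibble of (cleaned, resolved) occurrence records.
#' @param path output path; extension decides the delimiter (`.csv` comma,
#'   otherwise tab).
#' @return `path`, invisibly.
#' @export
write_checklist <- function(records, path) {
  if (nrow(records) == 0L) stop("refusing to write an empty checklist", call. = FALSE)
  out <- tibble::as_tibble(records)
  for (col in dwc_checklist_columns) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
  }
  out <- out[dwc_checklist_columns]
  # the published layout capitalises the event-date label
  names(out)[names(out) == "eventDate"] <- "EventDate"
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Write a cleaning ledger
#'
#' One row per (group, stage) with the input/kept/removed accounting and the
#' signed delta used by review additions.
#'
#' @param ledger a ledger tibble (see [run_cleaning()]).
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  readr::write_tsv(ledger, path, na = "")
  invisible(path)
}
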