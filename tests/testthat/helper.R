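# Fixture builders shared across the test files. Everything is generated in
# code; no data files are read.

toy_record <- function(catalogNumber, scientificName,
                       taxonRank = "SPECIES",
                       recordedBy = "A.C. Fictus", recordNumber = "1",
                       eventDate = "1995-06-01", locality = "Itatiaia, trilha",
                       collectionCode = "RB", group = "angiosperm", ...) {
  parts <- strsplit(scientificName, " ")[[1]]
  tibble::tibble(
    catalogNumber = catalogNumber,
    scientificName = scientificName,
    genus = parts[[1]],
    specificEpithet = if (length(parts) > 1) parts[[2]] else NA_character_,
    taxonRank = taxonRank,
    recordedBy = recordedBy,
    recordNumber = recordNumber,
    eventDate = eventDate,
    collectionYear = herbcat::parse_collection_year(eventDate),
    locality = locality,
    collectionCode = collectionCode,
    group = group,
    ...
  )
}

toy_records <- function(...) dplyr::bind_rows(...)

# a small backbone: three accepted species (two genera, one family shared by
# two of them), one synonym, one non-native entry
toy_backbone <- function() {
  herbcat::as_backbone(tibble::tibble(
    name = c("Aus bus", "Aus dus", "Cus ephemerus", "Aus cus"),
    author = c("L.", "L.", "Mez", "Taub."),
    status = c("accepted", "accepted", "accepted", "synonym"),
    acceptedName = c(NA, NA, NA, "Aus bus"),
    group = c("angiosperm", "angiosperm", "lycophyte_fern", "angiosperm"),
    family = c("Fusaceae", "Fusaceae", "Gusaceae", "Fusaceae"),
    origin = c("native", "cultivated", "native", "native"),
    endemicToCountry = c(TRUE, FALSE, FALSE, TRUE),
    lifeForms = c("tree|shrub", "herb", "herb", ""),
    vegetationTypes = c("floresta ombrófila densa",
                        "campo de altitude|inselberg",
                        "floresta ombrófila mista|campo de altitude", "")
  ))
}

toy_assessments <- function() {
  herbcat::as_assessments(tibble::tibble(
    speciesName = c("Aus bus", "Cus ephemerus"),
    category = c("EN", "VU")
  ))
}

toy_gazetteer <- function(policy = "keep_and_queue") {
  # "itatiai" is a prefix of the excluded "itatiaiuçu": records from there
  # carry conflicting evidence and must be queued, not silently dropped
  herbcat::gazetteer(include = c("itatiaia", "itatiai"),
                     exclude = c("bocaina", "itatiaiuçu"),
                     default_policy = policy)
}

# independent year oracle: brute-force scan for the first 4-digit token in
# the plausible range, written with base R only
oracle_year <- function(x) {
  ymax <- as.integer(format(Sys.Date(), "%Y"))
  vapply(as.character(x), function(s) {
    if (is.na(s)) return(NA_integer_)
    m <- regmatches(s, gregexpr("[0-9]{4}", s))[[1]]
    for (tok in m) {
      y <- as.integer(tok)
      # reject tokens embedded in longer digit runs
      if (grepl(paste0("[0-9]", tok), s) || grepl(paste0(tok, "[0-9]"), s)) next
      if (y >= 1750 && y <= ymax) return(y)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

# independent dedup oracle: group by the exact key tuple with split();
# representative = lexicographically smallest catalogNumber
oracle_dedup_kept <- function(records) {
  coll <- herbcat::normalize_collector(records$recordedBy)
  num <- ifelse(is.na(records$recordNumber), "", records$recordNumber)
  complete <- coll != "UNKNOWN" & num != "" & !is.na(records$collectionYear)
  kept <- records$catalogNumber[!complete]
  groups <- split(records$catalogNumber[complete],
                  paste(coll, num, records$collectionYear)[complete])
  sort(c(kept, vapply(groups, function(g) sort(g)[[1]], character(1)),
         use.names = FALSE))
}

# random occurrence records for property tests (collisions intended)
random_records <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    catalogNumber = sprintf("CAT%05d", sample(99999L, n)),
    scientificName = "Aus bus",
    specificEpithet = "bus",
    taxonRank = "SPECIES",
    recordedBy = sample(c("A.C. Fictus", "M. Silveira", "Fictus, A.C.", "", NA),
                        n, replace = TRUE),
    recordNumber = as.character(sample(c(1:8, NA), n, replace = TRUE)),
    collectionYear = sample(c(1940:1943, NA), n, replace = TRUE),
    group = "angiosperm"
  )
}
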