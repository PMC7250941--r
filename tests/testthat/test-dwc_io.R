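test_that("year extraction handles the common label dialects and agrees with a token-scan oracle", {
  expect_equal(parse_collection_year(c("1942-03-10", "10/03/1942", "1942")),
               c(1942L, 1942L, 1942L))
  expect_equal(parse_collection_year(c("1942-03", "s.d.", "", NA, "42")),
               c(1942L, NA, NA, NA, NA))
  # out-of-range tokens are not years
  expect_equal(parse_collection_year(c("1600", "3024")), c(NA_integer_, NA_integer_))

  set.seed(11)
  yrs <- sample(1750:2024, 1000, replace = TRUE)
  mo <- sprintf("%02d", sample(12, 1000, replace = TRUE))
  dy <- sprintf("%02d", sample(28, 1000, replace = TRUE))
  style <- sample(5, 1000, replace = TRUE)
  dates <- dplyr::case_when(
    style == 1 ~ paste(yrs, mo, dy, sep = "-"),
    style == 2 ~ paste(dy, mo, yrs, sep = "/"),
    style == 3 ~ as.character(yrs),
    style == 4 ~ paste0(mo, "/", substr(yrs, 3, 4)),      # 2-digit year
    TRUE ~ "sem data"
  )
  expect_equal(parse_collection_year(dates), oracle_year(dates))
})

test_that("occurrence reading populates fields, reports parsing, and never drops rows", {
  recs <- toy_records(
    toy_record("RB001", "Aus bus", eventDate = "1942-03-10",
               typeStatus = "holotype"),
    toy_record("RB002", "Aus dus", eventDate = "10/03/1995"),
    toy_record("RB003", "Cus ephemerus", eventDate = "s.d.")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_checklist(recs, path)

  back <- read_occurrences(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$collectionYear, c(1942L, 1995L, NA))
  expect_equal(back$typeStatus[1], "holotype")

  rep <- parse_report(back)
  expect_equal(rep$rows_read, 3L)
  expect_equal(rep$records, 3L)
  expect_equal(rep$year_unparseable, 1L)
})

test_that("an empty table with a header yields an empty collection and a zero report", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("catalogNumber", "scientificName", "EventDate"),
                   collapse = "\t"), path)
  out <- read_occurrences(path)
  expect_equal(nrow(out), 0L)
  expect_equal(parse_report(out)$records, 0L)
})

test_that("missing mandatory columns and duplicated barcodes are hard errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scientificName\tlocality", "Aus bus\tItatiaia"), path)
  expect_error(read_occurrences(path), "catalogNumber")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("catalogNumber\tscientificName",
               "RB001\tAus bus", "RB001\tAus dus"), path2)
  expect_error(read_occurrences(path2), "RB001")
})

test_that("a configurable column map ingests non-standard export headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("codbarras,nome,coletor,data",
               "J1,Aus bus,Fulano,1980"), path)
  d <- dwc_dialect(column_map = dwc_column_map(
    codbarras = "catalogNumber", nome = "scientificName",
    coletor = "recordedBy", data = "eventDate"))
  out <- read_occurrences(path, d)
  expect_equal(out$catalogNumber, "J1")
  expect_equal(out$collectionYear, 1980L)
})

test_that("checklist write/read round-trips field values, accents included", {
  recs <- toy_records(
    toy_record("RB010", "Aus bus", locality = "Véu da Noiva, Itatiaia",
               recordedBy = "J.P. Araújo"),
    toy_record("RB011", "Aus dus")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_checklist(recs, path)
  back <- read_occurrences(path)
  for (col in c("catalogNumber", "scientificName", "locality", "recordedBy",
                "taxonRank", "specificEpithet")) {
    expect_equal(back[[col]], recs[[col]], label = col)
  }
  # writing what was read reproduces the same file content
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_checklist(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(write_checklist(recs[0, ], path), "empty")
})

test_that("backbone loading enforces its referential invariants", {
  bb <- toy_backbone()
  expect_equal(nrow(bb), 4L)
  expect_equal(bb$acceptedName[bb$name == "Aus cus"], "Aus bus")
  expect_equal(bb$acceptedName[bb$status == "accepted"],
               bb$name[bb$status == "accepted"])
  # cultivated entries load as non-native
  expect_equal(bb$origin[bb$name == "Aus dus"], "non_native")
  expect_equal(bb$lifeForms[[1]], c("tree", "shrub"))

  chain <- tibble::tibble(
    name = c("Aus bus", "Aus cus", "Aus dus"),
    status = c("accepted", "synonym", "synonym"),
    acceptedName = c(NA, "Aus bus", "Aus cus"))
  expect_error(as_backbone(chain), "Aus cus")

  dup <- tibble::tibble(name = c("Aus bus", "Aus bus"),
                        status = "accepted", acceptedName = NA)
  expect_error(as_backbone(dup), "duplicate")

  # file round trip preserves entries
  path <- withr::local_tempfile(fileext = ".tsv")
  write_backbone(bb, path)
  back <- read_backbone(path)
  expect_equal(back$name, bb$name)
  expect_equal(back$vegetationTypes, bb$vegetationTypes)
  expect_equal(back$endemicToCountry, bb$endemicToCountry)
})

test_that("assessment tables validate categories and default to NE", {
  a <- toy_assessments()
  expect_equal(threat_category("Aus bus", a), "EN")
  expect_equal(threat_category("Aus missing", a), "NE")
  expect_error(as_assessments(tibble::tibble(speciesName = "x", category = "XX")),
               "XX")
  expect_error(as_assessments(tibble::tibble(speciesName = c("a", "a"),
                                             category = c("EN", "VU"))),
               "multiple")
})

test_that("ledger files carry one row per stage and replay printed arithmetic", {
  led <- ledger_replay("angiosperm", 10L, c(determination = 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ledger(led, path)
  lines <- readLines(path)
  expect_length(lines, 2L)

  led0 <- led[0, ]
  write_ledger(led0, path)
  expect_length(readLines(path), 1L)
})
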