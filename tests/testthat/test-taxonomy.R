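# independent fuzzy-match oracle: full edit-distance scan over the backbone,
# with genus and epithet distances computed separately and summed
oracle_match <- function(query, backbone, max_distance) {
  qf <- tolower(query)
  bf <- tolower(backbone$name)
  qg <- strsplit(qf, " ")[[1]]
  parts <- strsplit(bf, " ")
  d <- vapply(parts, function(p) {
    as.integer(utils::adist(qg[1], p[1]) +
               utils::adist(paste(qg[-1], collapse = " "),
                            paste(p[-1], collapse = " ")))
  }, integer(1))
  if (any(d == 0)) {
    hit <- which(d == 0)
    acc <- hit[backbone$status[hit] == "accepted"]
    h <- if (length(acc)) acc[[1]] else hit[[1]]
    return(list(accepted = backbone$acceptedName[h], distance = 0L))
  }
  if (min(d) > max_distance) return(list(accepted = NA_character_, distance = NA))
  near <- which(d == min(d))
  acc <- unique(backbone$acceptedName[near])
  list(accepted = if (length(acc) == 1) acc else NA_character_,
       distance = min(d))
}

test_that("exact matches resolve directly, synonyms to their accepted name", {
  bb <- toy_backbone()
  m <- match_name("Aus bus", bb)
  expect_equal(m$matchType, "exact_accepted")
  expect_equal(m$acceptedName, "Aus bus")
  expect_equal(m$editDistance, 0L)

  m2 <- match_name("Aus cus", bb)
  expect_equal(m2$matchType, "synonym")
  expect_equal(m2$acceptedName, "Aus bus")
  expect_equal(m2$editDistance, 0L)

  # case, accents and hybrid markers are ignored
  expect_equal(match_name("aus BUS", bb)$matchType, "exact_accepted")
  expect_equal(match_name("Aus ×bus", bb)$matchType, "exact_accepted")
  expect_error(match_name("", bb), "empty")
})

test_that("fuzzy matching agrees with an exhaustive edit-distance oracle", {
  bb <- toy_backbone()
  queries <- c("Aus bus", "Aus bos", "Aus cuss", "Cus ephemerux",
               "Aue bus", "Xus yus", "Aus duz", "Cuz ephemerus")
  for (q in queries) {
    got <- match_name(q, bb, max_distance = 1)
    want <- oracle_match(q, bb, 1)
    expect_equal(got$acceptedName, want$accepted, label = q)
    if (!is.na(want$accepted) && want$distance > 0) {
      expect_equal(got$editDistance, want$distance, label = q)
      expect_match(got$matchType, "^fuzzy")
    }
  }
})

test_that("matching at distance 0 is a pure dictionary lookup", {
  bb <- toy_backbone()
  queries <- c(bb$name, "Aus bos", "Aus buss", "Nope nope")
  for (q in queries) {
    got <- match_name(q, bb, max_distance = 0)
    in_dict <- tolower(q) %in% tolower(bb$name)
    expect_equal(got$matchType %in% c("exact_accepted", "synonym"), in_dict,
                 label = q)
  }
})

test_that("equally-near candidates with different accepted names are ambiguous", {
  bb <- as_backbone(tibble::tibble(
    name = c("Aus bus", "Aus bas", "Aus bis"),
    status = "accepted", acceptedName = NA_character_,
    group = "angiosperm", family = "Fusaceae"))
  m <- match_name("Aus bos", bb, max_distance = 1)
  expect_equal(m$matchType, "ambiguous")
  expect_true(is.na(m$acceptedName))
  expect_setequal(m$candidates[[1]], c("Aus bus", "Aus bas", "Aus bis"))

  # a synonym and its own accepted name both one edit away is not a tie
  bb2 <- as_backbone(tibble::tibble(
    name = c("Aus bus", "Aus bas"),
    status = c("accepted", "synonym"),
    acceptedName = c(NA, "Aus bus"),
    group = "angiosperm", family = "Fusaceae"))
  m2 <- match_name("Aus bos", bb2, max_distance = 1)
  expect_equal(m2$acceptedName, "Aus bus")
})

test_that("record resolution routes failures to the queue and loses nothing", {
  bb <- toy_backbone()
  recs <- toy_records(
    toy_record("RB1", "Aus bus"),
    toy_record("RB2", "Aus cus"),        # synonym
    toy_record("RB3", "Aus buz"),        # unique misspelling
    toy_record("RB4", "Zus zus")         # absent from the backbone
  )
  recs$speciesBinomial <- recs$scientificName
  out <- resolve_records(recs, bb, max_distance = 1)
  expect_equal(nrow(out$resolved) + nrow(out$unresolved), nrow(recs))
  expect_setequal(out$resolved$catalogNumber, c("RB1", "RB2", "RB3"))
  expect_equal(unique(out$resolved$acceptedName), "Aus bus")
  expect_equal(out$unresolved$catalogNumber, "RB4")
  expect_equal(sum(out$report$n), nrow(recs))
  # accepted names are always accepted backbone entries, never synonyms
  st <- bb$status[match(out$resolved$acceptedName, bb$name)]
  expect_true(all(st == "accepted"))
  # group comes from the accepted entry
  expect_equal(assign_group(c("Cus ephemerus", NA), bb),
               c("lycophyte_fern", "unknown"))
})

test_that("resolution is permutation-invariant", {
  bb <- toy_backbone()
  recs <- toy_records(
    toy_record("RB1", "Aus bus"), toy_record("RB2", "Aus buz"),
    toy_record("RB3", "Cus ephemerus"), toy_record("RB4", "Zus zus"))
  recs$speciesBinomial <- recs$scientificName
  a <- resolve_records(recs, bb, 1)
  b <- resolve_records(recs[4:1, ], bb, 1)
  expect_setequal(a$resolved$catalogNumber, b$resolved$catalogNumber)
  expect_equal(dplyr::arrange(a$report, matchType),
               dplyr::arrange(b$report, matchType))
})

test_that("review files re-admit, remove and add records with ledger entries", {
  bb <- toy_backbone()
  recs <- toy_records(
    toy_record("RB1", "Aus bus"),
    toy_record("RB2", "Zus zus"))
  recs$speciesBinomial <- recs$scientificName
  res <- resolve_records(recs, bb, 1)

  # empty review is the identity
  id <- apply_review(res$resolved, NULL, res$unresolved)
  expect_equal(id$records, res$resolved)

  review <- tibble::tibble(
    catalogNumber = c("RB2", "EXT1", "RB1"),
    action = c("accept_as", "add", "remove"),
    name = c("Zus zus", "Cus ephemerus", NA),
    group = c("angiosperm", "lycophyte_fern", NA)
  )
  out <- apply_review(res$resolved, review, res$unresolved)
  expect_setequal(out$records$catalogNumber, c("RB2", "EXT1"))
  expect_equal(out$records$acceptedName[out$records$catalogNumber == "RB2"],
               "Zus zus")
  led <- out$ledger
  expect_equal(led$removed[led$stage == "review_removals"], 1L)
  expect_equal(led$delta[led$stage == "review_additions"], 2L)
  validate_ledger(led)

  bad <- tibble::tibble(catalogNumber = "NOPE", action = "remove", name = NA)
  expect_error(apply_review(res$resolved, bad, res$unresolved), "NOPE")
})
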