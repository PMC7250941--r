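test_that("determination filter keeps species-level records and collapses infraspecifics", {
  recs <- toy_records(
    toy_record("RB001", "Aus bus"),
    toy_record("RB002", "Aus", taxonRank = "GENUS"),
    toy_record("RB003", "Aus bus var. cus", taxonRank = "VARIETY"),
    toy_record("RB004", "Fusaceae", taxonRank = "FAMILY"),
    toy_record("RB005", "Aus dus", taxonRank = "CF_SPECIES")  # unrecognised
  )
  out <- filter_determined(recs)
  expect_setequal(out$kept$catalogNumber, c("RB001", "RB003"))
  expect_equal(out$kept$speciesBinomial, c("Aus bus", "Aus bus"))
  expect_setequal(out$removed$removalReason[out$removed$catalogNumber == "RB005"],
                  "indeterminable_rank")
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(recs))
})

test_that("collector normalisation folds case, accents and punctuation but not initial order", {
  expect_equal(normalize_collector("A.C. Brade"), "ac brade")
  expect_equal(normalize_collector("BRADE, A. C."), "brade a c")
  expect_equal(normalize_collector(c("", NA, "  J.  Araújo ")),
               c("UNKNOWN", "UNKNOWN", "j araujo"))
})

test_that("locality screening applies exclude/include precedence and queues conflicts", {
  gaz <- toy_gazetteer()
  cases <- toy_records(
    toy_record("L1", "Aus bus",
               locality = "Parque Nacional do Itatiaia, trilha Véu da Noiva"),
    toy_record("L2", "Aus bus", locality = "Serra da Bocaina"),
    toy_record("L3", "Aus bus", locality = "Itatiaiuçu, MG"),
    toy_record("L4", "Aus bus", locality = "Fazenda sem nome"),
    toy_record("L5", "Aus bus", locality = "Campo da Bocaina, Itatiaia")
  )
  out <- filter_locality(cases, gaz)
  # include term matches on a word boundary -> kept
  expect_true("L1" %in% out$kept$catalogNumber)
  # exclude only -> removed
  expect_equal(out$removed$catalogNumber, "L2")
  # include matches only inside the excluded name -> queued, not dropped
  expect_true("L3" %in% out$queued$catalogNumber)
  # neither list, keep_and_queue -> kept and queued
  expect_true("L4" %in% out$kept$catalogNumber)
  expect_true("L4" %in% out$queued$catalogNumber)
  # exclude matches but a whole-word include match overrides -> kept, not queued
  expect_true("L5" %in% out$kept$catalogNumber)
  expect_false("L5" %in% out$queued$catalogNumber)

  drop_out <- filter_locality(cases, toy_gazetteer(policy = "drop"))
  expect_setequal(drop_out$removed$catalogNumber, c("L2", "L4"))
})

test_that("deduplication keeps one sheet per complete key, smallest barcode first", {
  recs <- toy_records(
    toy_record("RB200", "Aus bus", recordedBy = "Brade", recordNumber = "12345",
               eventDate = "1942", collectionCode = "RB"),
    toy_record("RB100", "Aus bus", recordedBy = "BRADE", recordNumber = "12345",
               eventDate = "10/03/1942", collectionCode = "R"),
    toy_record("RB300", "Aus bus", recordedBy = "Brade", recordNumber = "12345",
               eventDate = "1941")
  )
  out <- deduplicate(recs)
  # same collector+number, 1942 twice (merged across collections), 1941 kept
  expect_setequal(out$unique$catalogNumber, c("RB100", "RB300"))
  expect_equal(out$pairs, tibble::tibble(kept = "RB100", removed = "RB200"))
})

test_that("incomplete keys never merge", {
  recs <- toy_records(
    toy_record("RB1", "Aus bus", recordedBy = "", recordNumber = "7",
               eventDate = "1942"),
    toy_record("RB2", "Aus bus", recordedBy = "", recordNumber = "7",
               eventDate = "1942"),
    toy_record("RB3", "Aus bus", recordedBy = "Brade", recordNumber = NA,
               eventDate = "1942"),
    toy_record("RB4", "Aus bus", recordedBy = "Brade", recordNumber = NA,
               eventDate = "1942"),
    toy_record("RB5", "Aus bus", recordedBy = "Brade", recordNumber = "7",
               eventDate = ""),
    toy_record("RB6", "Aus bus", recordedBy = "Brade", recordNumber = "7",
               eventDate = "")
  )
  out <- deduplicate(recs)
  expect_equal(nrow(out$unique), 6L)
  expect_equal(nrow(out$removed), 0L)
})

test_that("deduplication matches a brute-force grouping oracle on random records", {
  for (seed in c(1, 2, 3)) {
    recs <- random_records(1000, seed)
    out <- deduplicate(recs)
    expect_equal(sort(out$unique$catalogNumber), oracle_dedup_kept(recs))
    expect_equal(nrow(out$unique) + nrow(out$removed), nrow(recs))
  }
})

test_that("deduplication is idempotent and permutation-invariant", {
  recs <- random_records(400, 9)
  once <- deduplicate(recs)
  twice <- deduplicate(once$unique)
  expect_equal(sort(twice$unique$catalogNumber), sort(once$unique$catalogNumber))
  expect_equal(nrow(twice$removed), 0L)

  set.seed(21)
  shuffled <- recs[sample(nrow(recs)), ]
  out_shuffled <- deduplicate(shuffled)
  expect_setequal(out_shuffled$unique$catalogNumber, once$unique$catalogNumber)
})

test_that("the cleaning protocol chains its stages and accounts for every record", {
  recs <- toy_records(
    toy_record("RB01", "Aus bus", recordNumber = "10"),
    toy_record("RB02", "Aus bus", recordedBy = "Brade", recordNumber = "5",
               eventDate = "1942"),
    toy_record("RB03", "Aus bus", recordedBy = "Brade", recordNumber = "5",
               eventDate = "1942", collectionCode = "R"),   # duplicate of RB02
    toy_record("RB04", "Aus dus", recordNumber = "11"),
    toy_record("RB05", "Aus dus", locality = "Serra da Bocaina",
               recordNumber = "12"),                        # out of area
    toy_record("RB06", "Cus ephemerus", recordNumber = "13"),
    toy_record("RB07", "Aus", taxonRank = "GENUS"),          # undetermined
    toy_record("RB08", "Fusaceae", taxonRank = "FAMILY"),    # undetermined
    toy_record("RB09", "Aus bus var. cus", taxonRank = "VARIETY",
               recordNumber = "14"),
    toy_record("RB10", "Cus ephemerus", recordedBy = "")
  )
  out <- run_cleaning(recs, toy_gazetteer())
  expect_equal(nrow(out$records), 6L)
  led <- out$ledger
  expect_equal(led$input, c(10L, 8L, 7L))
  expect_equal(led$kept, c(8L, 7L, 6L))
  expect_true(all(led$input == led$kept + led$removed))
  # telescoping: final kept = initial input - total removed
  expect_equal(unname(ledger_final(led)), led$input[1] - sum(led$removed))
  expect_equal(validate_ledger(led), TRUE)
})

test_that("cleaning an empty table produces empty stages", {
  recs <- toy_record("RB1", "Aus bus")[0, ]
  out <- run_cleaning(recs, toy_gazetteer())
  expect_equal(nrow(out$records), 0L)
  expect_true(all(out$ledger$input == 0L))
})
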