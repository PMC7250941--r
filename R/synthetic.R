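#' Configuration for the synthetic occurrence generator
#'
#' The generator emulates the structure of a digitised herbarium dump for a
#' protected area: a taxonomic backbone with synonyms and traits, a threat
#' assessment table, and an occurrence table with planted imperfections —
#' records determined only to genus, out-of-area localities, exact duplicate
#' sheets sharing the collector/number/year key, misspelled and synonymous
#' names, missing years and collectors. Defaults mirror a mid-sized survey:
#' 800 species dominated by angiosperms with a small gymnosperm contingent,
#' 5,000 records with a right-skewed records-per-species distribution, 10%
#' duplicate sheets, 5% misspellings at one edit, 2% out-of-area and 5%
#' genus-level records.
#'
#' @param seed integer seed; the whole run is deterministic given it.
#' @param n_species named integer vector of accepted species per group.
#' @param n_families,n_genera pool sizes for higher taxa.
#' @param n_records total number of base records (duplicates are added on
#'   top); must be at least the total species count.
#' @param synonyms_per_species expected synonyms per accepted species
#'   (Poisson, capped at 2).
#' @param duplicate_rate fraction of records given an exact key-sharing twin.
#' @param misspelling_rate fraction of records whose name is perturbed.
#' @param max_planted_distance edit distance of planted misspellings.
#' @param synonym_use_rate fraction of records citing a synonym of their
#'   species (where one exists).
#' @param out_of_area_rate fraction of records with an outside-area locality.
#' @param undetermined_rate fraction reduced to genus-level determination.
#' @param missing_year_rate,missing_collector_rate fractions with those
#'   fields blanked.
#' @param variety_rate fraction of clean records written as infraspecific
#'   determinations (collapsed to the binomial by the pipeline).
#' @param old_year_range,recent_year_range inclusive year intervals.
#' @param recent_share probability a record is dated in the recent range.
#' @param assessed_rate fraction of species present in the assessment table.
#' @param threat_category_distribution sampling weights over CR/EN/VU/NT/LC/DD
#'   for assessed species.
#' @param non_native_rate fraction of species flagged non-native.
#' @param n_priority_species number of species forced to satisfy the priority
#'   rule (single old record, category CR/EN/VU/DD).
#' @return a `herb_generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    n_species = c(angiosperm = 680L, gymnosperm = 7L, lycophyte_fern = 113L),
    n_families = 60L,
    n_genera = 290L,
    n_records = 5000L,
    synonyms_per_species = 0.3,
    duplicate_rate = 0.10,
    misspelling_rate = 0.05,
    max_planted_distance = 1L,
    synonym_use_rate = 0.10,
    out_of_area_rate = 0.02,
    undetermined_rate = 0.05,
    missing_year_rate = 0.01,
    missing_collector_rate = 0.01,
    variety_rate = 0.02,
    old_year_range = c(1871L, 1969L),
    recent_year_range = c(1970L, 2015L),
    recent_share = 0.75,
    assessed_rate = 0.5,
    threat_category_distribution = c(CR = 0.03, EN = 0.07, VU = 0.07,
                                     NT = 0.08, LC = 0.65, DD = 0.10),
    non_native_rate = 0.04,
    n_priority_species = 12L) {
  rates <- c(duplicate_rate, misspelling_rate, synonym_use_rate,
             out_of_area_rate, undetermined_rate, missing_year_rate,
             missing_collector_rate, variety_rate, recent_share,
             assessed_rate, non_native_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (sum(n_species) < 1L) stop("need at least one species", call. = FALSE)
  if (n_records < sum(n_species)) {
    stop("n_records must be at least the total species count", call. = FALSE)
  }
  structure(as.list(environment()), class = "herb_generator_config")
}

.syllables <- c("ba", "be", "bi", "bo", "bu", "ca", "ce", "co", "cu", "da",
                "de", "di", "do", "du", "fa", "fe", "fi", "fo", "ga", "ge",
                "gi", "go", "la", "le", "li", "lo", "lu", "ma", "me", "mi",
                "mo", "mu", "na", "ne", "ni", "no", "pa", "pe", "pi", "po",
                "ra", "re", "ri", "ro", "ru", "sa", "se", "si", "so", "su",
                "ta", "te", "ti", "to", "tu", "va", "ve", "vi", "vo", "za")

.make_words <- function(n, endings, min_dist = 3L, avoid = character()) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 60L * n) stop("name synthesis stalled", call. = FALSE)
    w <- paste0(paste(sample(.syllables, sample(2:3, 1L), replace = TRUE),
                      collapse = ""),
                sample(endings, 1L))
    pool <- c(out, avoid)
    if (length(pool) == 0L || min(utils::adist(w, pool)) >= min_dist) {
      out <- c(out, w)
    }
  }
  out
}

.capitalize <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

.include_localities <- c(
  "Parque Nacional do Itatiaia, trilha dos Três Picos",
  "PN do Itatiaia, próximo ao abrigo Rebouças",
  "Itatiaia, planalto, 2200 m",
  "Parque Nacional do Itatiaia, Véu da Noiva",
  "Itatiaia, estrada nova, km 12",
  "Parque Nacional do Itatiaia, Agulhas Negras"
)
.exclude_localities <- c(
  "Serra da Bocaina, campo aberto",
  "Visconde de Mauá, pastagem",
  "Serra do Caparaó, trilha principal"
)

.collector_pool <- function() {
  tibble::tibble(
    name = c("A.C. Fictus", "M. Silveira", "J.P. Araújo",
             "FICTUS, A. B.", "L. de Souza Prado", "R. Quintela",
             "C.N. Verdejo", "T. Mirandola", "E. Fontoura", "P. Sabiná",
             "D. Lourenço", "G. Pessanha", "V. Camposinho",
             "H. Ibérico", "S. Travassos", "N. Oliveto", "B. Madrugada",
             "K. Serranía", "W. Brejeiro", "F. Altamira"),
    weight = 1.6^(seq(20, 1)))
}

#' Generate a synthetic backbone, assessments and occurrence file
#'
#' Runs the whole generation process under one seeded random stream in a
#' fixed stage order, so identical configs give byte-identical outputs. All
#' synthesised names are pairwise at least three edits apart, so a planted
#' one-edit misspelling is always strictly closest to its true name and
#' resolution ground truth is unambiguous. Species forced to be conservation
#' priorities receive exactly one clean record dated in the old range and a
#' threat category in CR/EN/VU/DD.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory; when given, `occurrences.tsv`,
#'   `backbone.tsv`, `assessments.tsv` and `gazetteer.tsv` are written there.
#' @return list with `occurrences`, `backbone`, `assessments` (tibbles),
#'   `gazetteer`, `truth` (the manifest, see below) and `paths` (when `dir`
#'   was given). The truth manifest records the planted species set and
#'   per-group richness, per-record corruption flags, per-species record
#'   counts / temporal status / priority, collector counts and the peak
#'   collection year.
#' @export
generate_flora <- function(config = generator_config(), dir = NULL) {
  stopifnot(inherits(config, "herb_generator_config"))
  set.seed(config$seed)
  cfg <- config

  groups <- names(cfg$n_species)[cfg$n_species > 0L]
  n_sp_g <- cfg$n_species[groups]
  n_total <- sum(n_sp_g)

  ## --- higher taxa ---------------------------------------------------------
  fam_share <- pmax(1L, round(cfg$n_families * n_sp_g / n_total))
  gen_share <- pmax(1L, round(cfg$n_genera * n_sp_g / n_total))
  fam_names <- .capitalize(.make_words(sum(fam_share), endings = "aceae",
                                       min_dist = 1L))
  genus_words <- .make_words(sum(gen_share), endings = c("um", "ia", "us", "ea"))
  genera <- tibble::tibble(
    genus = .capitalize(genus_words),
    group = rep(groups, gen_share),
    family = NA_character_
  )
  fam_of_group <- split(fam_names, rep(groups, fam_share))
  for (g in groups) {
    rows <- genera$group == g
    genera$family[rows] <- sample(fam_of_group[[g]], sum(rows), replace = TRUE)
  }

  ## --- accepted species and synonyms --------------------------------------
  n_syn <- pmin(2L, stats::rpois(n_total, cfg$synonyms_per_species))
  epithets <- .make_words(n_total + sum(n_syn),
                          endings = c("ensis", "iana", "folia", "oides", "ata"))
  sp_gen_idx <- unlist(lapply(groups, function(g) {
    sample(which(genera$group == g), n_sp_g[[g]], replace = TRUE)
  }), use.names = FALSE)
  species <- tibble::tibble(
    name = paste(genera$genus[sp_gen_idx], epithets[seq_len(n_total)]),
    genus = genera$genus[sp_gen_idx],
    family = genera$family[sp_gen_idx],
    group = rep(groups, n_sp_g),
    n_synonyms = n_syn
  )
  lf_levels <- c("tree", "shrub", "subshrub", "liana", "herb")
  veg_labels <- default_vegetation_map()$label
  species$lifeForms <- lapply(seq_len(n_total), function(i) {
    if (species$group[i] == "gymnosperm") return("tree")
    sample(lf_levels, sample(1:2, 1L, prob = c(0.7, 0.3)))
  })
  species$vegetationTypes <- lapply(seq_len(n_total), function(i) {
    if (stats::runif(1) < 0.05) return(character())
    sample(veg_labels, sample(1:2, 1L, prob = c(0.6, 0.4)))
  })
  species$origin <- ifelse(stats::runif(n_total) < cfg$non_native_rate,
                           "non_native", "native")
  species$endemicToCountry <- species$origin == "native" &
    stats::runif(n_total) < 0.5

  syn_rows <- NULL
  if (sum(n_syn) > 0L) {
    syn_eps <- epithets[n_total + seq_len(sum(n_syn))]
    owner <- rep(seq_len(n_total), n_syn)
    syn_rows <- tibble::tibble(
      name = paste(species$genus[owner], syn_eps),
      author = "Synth.",
      status = "synonym",
      acceptedName = species$name[owner],
      group = species$group[owner],
      family = species$family[owner],
      origin = species$origin[owner],
      endemicToCountry = species$endemicToCountry[owner],
      lifeForms = species$lifeForms[owner],
      vegetationTypes = species$vegetationTypes[owner]
    )
  }
  backbone <- dplyr::bind_rows(
    tibble::tibble(
      name = species$name, author = "Synth.", status = "accepted",
      acceptedName = species$name, group = species$group,
      family = species$family, origin = species$origin,
      endemicToCountry = species$endemicToCountry,
      lifeForms = species$lifeForms, vegetationTypes = species$vegetationTypes
    ),
    syn_rows
  )
  backbone <- as_backbone(backbone)

  ## --- assessments and forced priority species ----------------------------
  assessed <- stats::runif(n_total) < cfg$assessed_rate
  cat_pool <- names(cfg$threat_category_distribution)
  category <- rep("NE", n_total)
  category[assessed] <- sample(cat_pool, sum(assessed), replace = TRUE,
                               prob = cfg$threat_category_distribution)
  eligible <- which(category %in% c("CR", "EN", "VU", "DD"))
  if (length(eligible) < cfg$n_priority_species) {
    stop("infeasible config: only ", length(eligible),
         " species carry a priority-eligible category but n_priority_species = ",
         cfg$n_priority_species, call. = FALSE)
  }
  priority_idx <- sort(sample(eligible, cfg$n_priority_species))
  species$category <- category
  assessments <- as_assessments(tibble::tibble(
    speciesName = species$name[assessed & category != "NE"],
    category = category[assessed & category != "NE"]
  ))

  ## --- base records --------------------------------------------------------
  is_priority_sp <- seq_len(n_total) %in% priority_idx
  counts <- integer(n_total)
  counts[is_priority_sp] <- 1L
  free <- which(!is_priority_sp)
  spare <- cfg$n_records - cfg$n_priority_species - length(free)
  w <- stats::rgamma(length(free), shape = 0.5)
  counts[free] <- 1L + if (spare > 0L) {
    as.integer(stats::rmultinom(1L, spare, prob = w))
  } else 0L

  sp_of_rec <- rep(seq_len(n_total), counts)
  n_rec <- length(sp_of_rec)
  recs <- tibble::tibble(
    spIdx = sp_of_rec,
    speciesName = species$name[sp_of_rec],
    group = species$group[sp_of_rec],
    priority_sp = is_priority_sp[sp_of_rec]
  )

  pool <- .collector_pool()
  coll_i <- sample(nrow(pool), n_rec, replace = TRUE, prob = pool$weight)
  recs$recordedBy <- pool$name[coll_i]
  recs$recordNumber <- as.character(stats::ave(seq_len(n_rec), coll_i,
                                               FUN = seq_along))

  yrs_old <- cfg$old_year_range[1]:cfg$old_year_range[2]
  yrs_new <- cfg$recent_year_range[1]:cfg$recent_year_range[2]
  peak <- sample(yrs_new, 1L)
  w_new <- ifelse(yrs_new == peak, 4, 1)
  is_recent <- stats::runif(n_rec) < cfg$recent_share & !recs$priority_sp
  recs$year <- ifelse(is_recent,
                      sample(yrs_new, n_rec, replace = TRUE, prob = w_new),
                      sample(yrs_old, n_rec, replace = TRUE))

  ## --- corruption classes (disjoint, priority records exempt) -------------
  classes <- c("none", "undetermined", "out_of_area", "missing_year",
               "missing_collector", "misspelled", "synonym_use")
  probs <- c(NA, cfg$undetermined_rate, cfg$out_of_area_rate,
             cfg$missing_year_rate, cfg$missing_collector_rate,
             cfg$misspelling_rate, cfg$synonym_use_rate)
  probs[1] <- 1 - sum(probs[-1])
  if (probs[1] < 0) stop("corruption rates sum to more than 1", call. = FALSE)
  recs$class <- sample(classes, n_rec, replace = TRUE, prob = probs)
  recs$class[recs$priority_sp] <- "none"
  # synonym use degrades to none where the species has no synonym
  no_syn <- recs$class == "synonym_use" & species$n_synonyms[recs$spIdx] == 0L
  recs$class[no_syn] <- "none"

  ## --- render the written fields ------------------------------------------
  recs$writtenName <- recs$speciesName
  recs$taxonRank <- "SPECIES"
  recs$specificEpithet <- vapply(strsplit(recs$speciesName, " "), `[[`, "", 2L)
  recs$infraspecificEpithet <- NA_character_
  recs$genus <- species$genus[recs$spIdx]
  recs$family <- species$family[recs$spIdx]
  recs$locality <- sample(.include_localities, n_rec, replace = TRUE)
  recs$lifeForm <- vapply(recs$spIdx, function(i) {
    lf <- species$lifeForms[[i]]
    if (stats::runif(1) < 0.5) NA_character_ else sample(lf, 1L)
  }, character(1))

  # infraspecific determinations among clean records
  vr <- recs$class == "none" & !recs$priority_sp &
    stats::runif(n_rec) < cfg$variety_rate
  recs$writtenName[vr] <- paste(recs$speciesName[vr], "var. minor")
  recs$taxonRank[vr] <- "VARIETY"
  recs$infraspecificEpithet[vr] <- "minor"

  # planted misspellings: perturb the epithet by max_planted_distance edits
  perturb <- function(word, d) {
    for (k in seq_len(d)) {
      pos <- sample(nchar(word), 1L)
      op <- sample(c("sub", "ins", "del"), 1L)
      letters_pool <- setdiff(letters, substr(word, pos, pos))
      word <- switch(op,
        sub = paste0(substr(word, 1, pos - 1), sample(letters_pool, 1L),
                     substr(word, pos + 1, nchar(word))),
        ins = paste0(substr(word, 1, pos), sample(letters, 1L),
                     substr(word, pos + 1, nchar(word))),
        del = if (nchar(word) > 3L) {
          paste0(substr(word, 1, pos - 1), substr(word, pos + 1, nchar(word)))
        } else word
      )
    }
    word
  }
  ms <- which(recs$class == "misspelled")
  for (i in ms) {
    ep <- perturb(recs$specificEpithet[i], cfg$max_planted_distance)
    recs$writtenName[i] <- paste(recs$genus[i], ep)
    recs$specificEpithet[i] <- ep
  }

  # synonym usage
  syn_map <- if (!is.null(syn_rows)) split(syn_rows$name, syn_rows$acceptedName)
             else list()
  su <- which(recs$class == "synonym_use")
  for (i in su) {
    syn <- sample(syn_map[[recs$speciesName[i]]], 1L)
    recs$writtenName[i] <- syn
    recs$specificEpithet[i] <- strsplit(syn, " ")[[1]][2]
  }

  # genus-level determinations
  ud <- recs$class == "undetermined"
  recs$writtenName[ud] <- recs$genus[ud]
  recs$taxonRank[ud] <- "GENUS"
  recs$specificEpithet[ud] <- NA_character_

  oa <- recs$class == "out_of_area"
  recs$locality[oa] <- sample(.exclude_localities, sum(oa), replace = TRUE)

  recs$year[recs$class == "missing_year"] <- NA_integer_
  recs$recordedBy[recs$class == "missing_collector"] <- NA_character_

  dialect <- sample(c("iso", "dmy", "bare"), n_rec, replace = TRUE)
  mo <- sample(12L, n_rec, replace = TRUE)
  dy <- sample(28L, n_rec, replace = TRUE)
  recs$eventDate <- dplyr::case_when(
    is.na(recs$year) ~ NA_character_,
    dialect == "iso" ~ sprintf("%d-%02d-%02d", recs$year, mo, dy),
    dialect == "dmy" ~ sprintf("%02d/%02d/%d", dy, mo, recs$year),
    TRUE ~ as.character(recs$year)
  )

  recs$catalogNumber <- sprintf("RB%07d", seq_len(n_rec))
  recs$collectionCode <- "RB"
  recs$isTwin <- FALSE

  ## --- duplicate twins ------------------------------------------------------
  n_twins <- round(cfg$duplicate_rate * n_rec)
  cand <- which(recs$class == "none" & !recs$priority_sp)
  if (n_twins > length(cand)) {
    stop("infeasible config: not enough clean records to host ", n_twins,
         " duplicate twins", call. = FALSE)
  }
  twin_src <- sample(cand, n_twins)
  twins <- recs[twin_src, , drop = FALSE]
  if (n_twins > 0L) {
    twins$catalogNumber <- sprintf("RB%07d", n_rec + seq_len(n_twins))
    twins$collectionCode <- sample(c("R", "HB"), n_twins, replace = TRUE)
    twins$isTwin <- TRUE
  }
  recs <- dplyr::bind_rows(recs, twins)

  ## --- occurrence table in file layout -------------------------------------
  lat <- round(-22.4 + stats::rnorm(nrow(recs), 0, 0.05), 4)
  lon <- round(-44.6 + stats::rnorm(nrow(recs), 0, 0.05), 4)
  drop_coord <- stats::runif(nrow(recs)) < 0.1
  occurrences <- tibble::tibble(
    taxonID = sprintf("sp%04d", recs$spIdx),
    scientificName = ifelse(recs$taxonRank == "GENUS", recs$writtenName,
                            paste(recs$writtenName, "Synth.")),
    kingdom = "Plantae",
    family = recs$family,
    genus = recs$genus,
    specificEpithet = recs$specificEpithet,
    infraspecificEpithet = recs$infraspecificEpithet,
    scientificNameAuthorship = ifelse(recs$taxonRank == "GENUS",
                                      NA_character_, "Synth."),
    modified = "2020-01-01",
    rightsHolder = "Herbarium Syntheticum",
    typeStatus = NA_character_,
    taxonRank = recs$taxonRank,
    collectionCode = recs$collectionCode,
    catalogNumber = recs$catalogNumber,
    locality = recs$locality,
    recordedBy = recs$recordedBy,
    EventDate = recs$eventDate,
    verbatimLongitude = ifelse(drop_coord, NA_real_, lon),
    verbatimLatitude = ifelse(drop_coord, NA_real_, lat),
    recordNumber = recs$recordNumber,
    group = recs$group,
    lifeForm = recs$lifeForm
  )

  gaz <- gazetteer(include = "itatiaia",
                   exclude = c("bocaina", "mauá", "caparaó"))

  ## --- truth manifest -------------------------------------------------------
  surviving <- recs$class != "undetermined" & recs$class != "out_of_area"
  final <- surviving & !recs$isTwin
  fin <- recs[final, , drop = FALSE]

  sp_present <- species[species$name %in% unique(fin$speciesName), , drop = FALSE]
  rich <- sp_present |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(nSpecies = dplyr::n_distinct(.data$name),
                     nGenera = dplyr::n_distinct(.data$genus),
                     nFamilies = dplyr::n_distinct(.data$family),
                     .groups = "drop")

  age <- record_age_class(fin$year)
  sp_stats <- fin |>
    dplyr::mutate(.age = age) |>
    dplyr::group_by(.data$speciesName) |>
    dplyr::summarise(group = dplyr::first(.data$group),
                     recordCount = dplyr::n(),
                     temporalStatus = species_temporal_status(.data$.age),
                     .groups = "drop")
  sp_stats$threatCategory <- threat_category(sp_stats$speciesName, assessments)
  sp_stats$priority <- flag_priority(sp_stats$recordCount,
                                     sp_stats$temporalStatus,
                                     sp_stats$threatCategory)

  coll <- fin |>
    dplyr::count(collector = normalize_collector(.data$recordedBy),
                 name = "records") |>
    dplyr::arrange(dplyr::desc(.data$records), .data$collector)

  yr_tab <- table(fin$year[!is.na(fin$year)])
  peak_true <- as.integer(names(yr_tab)[which.max(yr_tab)])

  truth <- list(
    species = sp_present[c("name", "group", "family", "genus", "category")] |>
      dplyr::rename(speciesName = "name"),
    richness = rich,
    record_flags = tibble::tibble(
      catalogNumber = recs$catalogNumber,
      speciesName = recs$speciesName,
      group = recs$group,
      class = recs$class,
      isDuplicateTwin = recs$isTwin,
      year = recs$year
    ),
    n_duplicate_twins = n_twins,
    n_out_of_area = sum(recs$class == "out_of_area"),
    n_undetermined = sum(recs$class == "undetermined"),
    species_stats = sp_stats,
    priority_species = sp_stats$speciesName[sp_stats$priority],
    forced_priority = species$name[priority_idx],
    collector_counts = coll,
    peak_year = peak_true,
    n_records_written = nrow(recs),
    n_final_records = nrow(fin)
  )

  out <- list(occurrences = occurrences, backbone = backbone,
              assessments = assessments, gazetteer = gaz, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      occurrences = file.path(dir, "occurrences.tsv"),
      backbone = file.path(dir, "backbone.tsv"),
      assessments = file.path(dir, "assessments.tsv"),
      gazetteer = file.path(dir, "gazetteer.tsv")
    )
    readr::write_tsv(occurrences, paths$occurrences, na = "")
    write_backbone(backbone, paths$backbone)
    readr::write_tsv(assessments, paths$assessments, na = "")
    readr::write_tsv(
      tibble::tibble(term = c("itatiaia", "bocaina", "mauá", "caparaó"),
                     role = c("include", "exclude", "exclude", "exclude")),
      paths$gazetteer, na = "")
    out$paths <- paths
  }
  out
}

#' Check pipeline outputs against the generator's truth manifest
#'
#' Compares a full pipeline run on generated files with what the generator
#' planted: the surviving species set, per-group richness, the three
#' cleaning-stage removal counts, name-resolution outcomes, per-species
#' temporal statuses, the priority set, per-collector record counts and the
#' peak collection year. Every comparison is exact.
#'
#' @param result a `herb_catalogue` from [run_catalogue()].
#' @param truth the `truth` element returned by [generate_flora()].
#' @return tibble (`check`, `pass`, `expected`, `observed`); attribute
#'   `"all_pass"` gives the conjunction.
#' @export
verify_recovery <- function(result, truth) {
  checks <- list()
  same <- function(x, y) {
    if (is.data.frame(x) && is.data.frame(y)) {
      x <- as.data.frame(x, stringsAsFactors = FALSE)
      y <- as.data.frame(y, stringsAsFactors = FALSE)
      rownames(x) <- NULL
      rownames(y) <- NULL
      return(isTRUE(all.equal(x, y, check.attributes = FALSE)))
    }
    isTRUE(all.equal(x, y))
  }
  fmt <- function(x) {
    if (is.data.frame(x)) paste0("<", nrow(x), " x ", ncol(x), " table>")
    else paste(format(x), collapse = ",")
  }
  add <- function(name, expected, observed) {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = name, pass = same(expected, observed),
      expected = fmt(expected), observed = fmt(observed))
  }

  cat_tab <- result$catalogue
  add("species_set",
      sort(truth$species$speciesName), sort(cat_tab$speciesName))

  rich_obs <- result$records |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      nSpecies = dplyr::n_distinct(.data$acceptedName),
      nGenera = dplyr::n_distinct(vapply(strsplit(.data$acceptedName, " "),
                                         `[[`, "", 1L)),
      nFamilies = dplyr::n_distinct(.data$acceptedFamily),
      .groups = "drop") |>
    dplyr::arrange(.data$group)
  add("richness_by_group",
      dplyr::arrange(truth$richness, .data$group), rich_obs)

  led <- result$ledger
  stage_removed <- function(stage) {
    as.integer(sum(led$removed[led$stage == stage]))
  }
  add("determination_removals", as.integer(truth$n_undetermined),
      stage_removed("determination"))
  add("locality_removals", as.integer(truth$n_out_of_area),
      stage_removed("locality"))
  add("dedup_removals", as.integer(truth$n_duplicate_twins),
      stage_removed("duplicates"))

  # every surviving record resolved to its planted species
  joined <- dplyr::inner_join(
    result$records[c("catalogNumber", "acceptedName")],
    truth$record_flags[c("catalogNumber", "speciesName")],
    by = "catalogNumber")
  add("resolution_outcomes",
      nrow(joined), sum(joined$acceptedName == joined$speciesName))

  ts_obs <- cat_tab[order(cat_tab$speciesName),
                    c("speciesName", "recordCount", "temporalStatus")]
  ts_true <- truth$species_stats[order(truth$species_stats$speciesName),
                                 c("speciesName", "recordCount",
                                   "temporalStatus")]
  add("temporal_statuses", ts_true, tibble::as_tibble(ts_obs))

  add("priority_set", sort(truth$priority_species),
      sort(cat_tab$speciesName[cat_tab$priority]))

  add("collector_counts", truth$collector_counts,
      collector_stats(result$records))

  add("peak_year", truth$peak_year,
      peak_year(temporal_profile(result$records)))

  out <- dplyr::bind_rows(checks)
  attr(out, "all_pass") <- all(out$pass)
  out
}
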