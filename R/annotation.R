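#' Default vegetation-label map
#'
#' Maps the flora's verbatim vegetation-type labels onto the binary
#' forest/grassland classification used by the catalogue (all forest types
#' count as forest; all grassland types and inselbergs count as grassland).
#' The map ships as an editable table; extend it for backbones using other
#' label vocabularies.
#'
#' @return tibble with columns `label`, `kind` (`forest`/`grassland`).
#' @export
default_vegetation_map <- function() {
  tibble::tribble(
    ~label, ~kind,
    "floresta ombrófila densa",        "forest",
    "floresta ombrófila mista",        "forest",
    "floresta estacional semidecidual",     "forest",
    "floresta altomontana",                 "forest",
    "floresta com araucária",          "forest",
    "campo de altitude",                    "grassland",
    "campo rupestre",                       "grassland",
    "campo limpo",                          "grassland",
    "inselberg",                            "grassland"
  )
}

#' Classify a species' vegetation types as forest, grassland or both
#'
#' @param types character vector of backbone vegetation-type labels for one
#'   species (or a list of such vectors for many species).
#' @param mapping label map, see [default_vegetation_map()].
#' @param unmapped what to do with labels absent from the map: `"ignore"`
#'   (warn once and skip them) or `"error"`.
#' @return `"forest"` if only forest labels, `"grassland"` if only grassland
#'   labels, `"both"` if both kinds occur, `"no_info"` if no (mapped) labels.
#' @export
classify_vegetation <- function(types, mapping = default_vegetation_map(),
                                unmapped = c("ignore", "error")) {
  unmapped <- match.arg(unmapped)
  if (is.list(types)) {
    return(vapply(types, classify_vegetation, character(1),
                  mapping = mapping, unmapped = unmapped))
  }
  types <- types[!is.na(types) & types != ""]
  kinds <- mapping$kind[match(fold_text(types), fold_text(mapping$label))]
  if (anyNA(kinds)) {
    missing <- unique(types[is.na(kinds)])
    if (unmapped == "error") {
      stop("unmapped vegetation label(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    warning("ignoring unmapped vegetation label(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
    kinds <- kinds[!is.na(kinds)]
  }
  has_f <- "forest" %in% kinds
  has_g <- "grassland" %in% kinds
  if (has_f && has_g) "both"
  else if (has_f) "forest"
  else if (has_g) "grassland"
  else "no_info"
}

.life_form_precedence <- c("tree", "shrub", "subshrub", "liana", "herb")

#' Pick one life form per species
#'
#' The backbone may list several life forms for a species. A single listed
#' form is taken as-is. With several, the most frequent life form observed on
#' the species' own herbarium records (restricted to the backbone's set)
#' decides; frequency ties, or absent record evidence, fall back on a fixed
#' precedence (tree > shrub > subshrub > liana > herb). A species with no
#' backbone forms takes the most frequent record observation, or `no_info`
#' when there is no evidence at all.
#'
#' @param backbone_forms character vector of life forms from the backbone.
#' @param record_forms character vector of per-record life-form observations
#'   for the species (may be empty).
#' @param precedence tie-break order.
#' @return one of `tree`, `shrub`, `subshrub`, `liana`, `herb`, `no_info`.
#' @export
classify_life_form <- function(backbone_forms, record_forms = character(),
                               precedence = .life_form_precedence) {
  bb <- unique(backbone_forms[!is.na(backbone_forms) & backbone_forms != ""])
  obs <- record_forms[!is.na(record_forms) & record_forms != ""]
  if (length(bb) == 1L) return(bb)
  pool <- if (length(bb)) bb else unique(obs)
  if (length(pool) == 0L) return("no_info")
  obs <- obs[obs %in% pool]
  if (length(obs)) {
    freq <- table(obs)
    top <- names(freq)[freq == max(freq)]
    if (length(top) == 1L) return(top)
    pool <- top
  }
  pool[order(match(pool, precedence))][1L]
}

#' Annotate species with traits and threat status
#'
#' For each accepted species, copies origin and endemism from the backbone
#' (cultivated or naturalised entries are non-native), attaches the threat
#' category from the assessment table (`NE` when absent), and derives the
#' vegetation class and life form with [classify_vegetation()] and
#' [classify_life_form()]. Species absent from the backbone — possible only
#' for review-added records — get `no_info`/`unknown` traits with a warning,
#' unless the review supplied traits through `extra_traits`.
#'
#' @param species character vector of accepted binomials.
#' @param backbone a `herb_backbone`.
#' @param assessments assessment tibble (see [read_assessments()]).
#' @param records optional clean records tibble; a `lifeForm` column, when
#'   present, supplies the per-record life-form evidence for the majority
#'   rule.
#' @param vegetation_map label map for [classify_vegetation()].
#' @param extra_traits optional tibble of reviewer-supplied traits
#'   (`speciesName` plus any of `origin`, `endemicToCountry`,
#'   `threatCategory`, `lifeForm`).
#' @return tibble: `speciesName`, `vegetationClass`, `lifeForm`, `origin`,
#'   `endemicToCountry`, `threatCategory`.
#' @export
annotate_species <- function(species, backbone, assessments,
                             records = NULL,
                             vegetation_map = default_vegetation_map(),
                             extra_traits = NULL) {
  species <- unique(species)
  idx <- match(species, backbone$name)
  absent <- is.na(idx)
  if (any(absent)) {
    warning("species absent from backbone (traits set to no_info/unknown): ",
            paste(species[absent], collapse = ", "), call. = FALSE)
  }

  obs_by_species <- list()
  if (!is.null(records) && "lifeForm" %in% names(records)) {
    keyed <- records[!is.na(records$lifeForm) & records$lifeForm != "", ]
    obs_by_species <- split(keyed$lifeForm, keyed$acceptedName)
  }

  veg <- character(length(species))
  lf <- character(length(species))
  for (i in seq_along(species)) {
    if (absent[i]) {
      veg[i] <- "no_info"
      lf[i] <- classify_life_form(character(),
                                  obs_by_species[[species[i]]] %||% character())
    } else {
      veg[i] <- classify_vegetation(backbone$vegetationTypes[[idx[i]]],
                                    mapping = vegetation_map)
      lf[i] <- classify_life_form(backbone$lifeForms[[idx[i]]],
                                  obs_by_species[[species[i]]] %||% character())
    }
  }

  out <- tibble::tibble(
    speciesName = species,
    vegetationClass = veg,
    lifeForm = lf,
    origin = ifelse(absent, NA_character_, backbone$origin[idx]),
    endemicToCountry = ifelse(absent, NA, backbone$endemicToCountry[idx]),
    threatCategory = threat_category(species, assessments)
  )

  if (!is.null(extra_traits) && nrow(extra_traits)) {
    for (i in seq_len(nrow(extra_traits))) {
      j <- which(out$speciesName == extra_traits$speciesName[i])
      if (!length(j)) next
      for (col in intersect(c("origin", "endemicToCountry", "threatCategory",
                              "lifeForm"), names(extra_traits))) {
        val <- extra_traits[[col]][i]
        if (!is.na(val)) out[[col]][j] <- val
      }
    }
  }
  out
}
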