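#' Case- and accent-insensitive folding
#'
#' Lower-cases, transliterates accented characters to ASCII and collapses
#' whitespace. Used everywhere two pieces of label text are compared
#' (localities, gazetteer terms, scientific names); stored values keep their
#' accents untouched.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @keywords internal
fold_text <- function(x) {
  x <- stringi::stri_trans_general(as.character(x), "Latin-ASCII")
  x <- tolower(x)
  stringr::str_squish(x)
}

#' Normalise a verbatim collector string into a dedup key
#'
#' The duplicate key is (collector, collector number, year); collector strings
#' on herbarium labels vary in case, accents and punctuation ("A.C. Brade",
#' "BRADE, A. C."). Normalisation case-folds, strips accents, deletes
#' punctuation and collapses whitespace. It deliberately does not reorder
#' initials, so "Brade, A.C." and "A.C. Brade" remain distinct keys
#' (conservative under-merging; such cases surface in review, not in silent
#' merges).
#'
#' @param name character vector of verbatim collector names.
#' @return character vector of keys; empty or missing input yields the
#'   distinguished token `"UNKNOWN"`.
#' @examples
#' normalize_collector(c("A.C. Brade", "BRADE, A. C.", ""))
#' @export
normalize_collector <- function(name) {
  out <- stringi::stri_trans_general(as.character(name), "Latin-ASCII")
  out <- tolower(out)
  out <- stringr::str_remove_all(out, "[[:punct:]]")
  out <- stringr::str_squish(out)
  out[is.na(name) | out == ""] <- "UNKNOWN"
  out
}

# earliest plausible herbarium collection year
.year_floor <- 1750L

#' Extract a collection year from a verbatim event date
#'
#' Scans the string for four-digit tokens and returns the first one that is a
#' plausible collection year (between 1750 and the current year). This single
#' rule covers ISO-8601 full and partial dates ("1942-03-10", "1942-03"),
#' day-first dates ("10/03/1942") and bare years ("1942"); anything without an
#' in-range token (e.g. "s.d.", two-digit years) yields `NA`.
#'
#' @param x character vector of verbatim dates.
#' @return integer vector of years, `NA` where no year could be extracted.
#' @examples
#' parse_collection_year(c("1942-03-10", "10/03/1942", "1942", "s.d."))
#' @export
parse_collection_year <- function(x) {
  x <- as.character(x)
  toks <- stringr::str_extract_all(x, "(?<!\\d)\\d{4}(?!\\d)")
  ymax <- as.integer(format(Sys.Date(), "%Y"))
  vapply(toks, function(tk) {
    if (length(tk) == 0L) return(NA_integer_)
    y <- suppressWarnings(as.integer(tk))
    y <- y[!is.na(y) & y >= .year_floor & y <= ymax]
    if (length(y) == 0L) NA_integer_ else y[[1L]]
  }, integer(1))
}

#' Collapse a scientific name to its binomial
#'
#' Drops authorship tails and infraspecific parts, keeping genus + specific
#' epithet; hybrid markers are removed. Species-level logic downstream
#' (matching, catalogue rows) always works on binomials.
#'
#' @param name character vector of verbatim scientific names.
#' @return character vector of binomials ("" if no epithet).
#' @keywords internal
collapse_binomial <- function(name) {
  name <- stringr::str_remove_all(as.character(name), "×")
  name <- stringr::str_squish(name)
  parts <- stringr::str_split(name, "\\s+")
  vapply(parts, function(p) {
    p <- p[p != ""]
    if (length(p) == 0L) return("")
    if (length(p) == 1L) return(p[[1L]])
    paste(p[[1L]], p[[2L]])
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
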