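---
title: "From herbarium export to protected-area catalogue: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From herbarium export to protected-area catalogue: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbcat)
```

## The problem

A digitised herbarium export for a region is a table of vouchers, not a
species list. Between the two stand four systematic defects: sheets
determined only to family or genus; records whose locality text places them
outside the target area; duplicate sheets from a single gathering distributed
across collections; and names that are synonyms, misspellings or otherwise
absent from the current taxonomy. `herbcat` models the standard curation
protocol as a typed pipeline whose every step is separately testable, and
whose record accounting is explicit enough to audit.

The guiding principle throughout is *conservative automation*: wherever an
automatic rule would have to guess (conflicting locality evidence, ambiguous
fuzzy matches, partial duplicate keys), the pipeline refuses to guess and
instead routes the record to a review queue, mirroring the manual
taxonomist pass that every real curation effort ends with.

## Cleaning model

**Determination.** A record is species-level when it has a specific epithet
and its rank is species or below (or blank). Infraspecific determinations
are kept but collapsed to the binomial, because the catalogue tracks species,
not infraspecific taxa. Unrecognised rank strings are treated as undetermined
but counted separately in the ledger reason, so a dialect problem in the
source export is visible rather than silent.

**Locality.** The source records carry verbatim locality strings and largely
unusable coordinates, so screening is textual: a gazetteer of include
(inside-area) and exclude (outside-area) substrings, matched
case- and accent-insensitively. The precedence rule is:

* an exclude match with an include term matching *on a word boundary* keeps
  the record (whole-word inside evidence wins);
* an exclude match with only a partial include match (e.g. an include term
  that is a prefix of a different, excluded place name) queues the record;
* an exclude match alone removes;
* no match either way follows the gazetteer's default policy, which defaults
  to *keep and queue* — the text filter alone is known to be fallible, so
  unconfirmed records stay in the pipeline but are exported for review.

**Duplicates.** The herbarium duplicate key is (collector, collector number,
collection year). Collector strings are normalised (case-folded,
accent-stripped, punctuation deleted, whitespace collapsed) before keying;
initial reordering is deliberately *not* attempted, so "Brade, A.C." and
"A.C. Brade" form different keys. That under-merges relative to an expert
eye, which we prefer to fabricating links; the cost is visible in collector
statistics rather than hidden in silently merged gatherings. Records missing
any key component are never merged. Among sheets sharing a complete key, the
one with the lexicographically smallest barcode is kept — an arbitrary but
deterministic and permutation-invariant choice. Merging is allowed across
collection codes, since that is precisely what herbarium duplicates are.

**Ledger.** Every stage appends `(group, stage, input, kept, removed)` with
`input = kept + removed` enforced, and stages chain (`kept` of one equals
`input` of the next; review additions enter through a signed `delta` so a
stage can never claim `kept > input`). `ledger_replay()` rebuilds a ledger
from published stage counts, which makes flow-diagram arithmetic directly
checkable.

## Name resolution

Matching works on binomials, case- and accent-insensitively, with hybrid
markers stripped; author strings are ignored for matching but preserved for
output (authorship formatting is too heterogeneous to key on). The
preference order is exact-accepted, exact-synonym, fuzzy. Fuzzy search
computes Levenshtein distances on genus and epithet separately and sums
them; the budget `max_distance` defaults to 1 edit, the smallest budget that
absorbs single-keystroke digitisation errors while keeping false merges
unlikely in a realistically spaced backbone. Equally-near candidates that
resolve to *different* accepted names are never auto-broken: the match is
ambiguous and goes to review. Candidates that are merely different entry
points to the same accepted name (a synonym and its accepted name both one
edit away) are not treated as a tie, since every resolution of the tie gives
the same answer.

The review file is the interface for expert decisions the automation refuses
to make: `accept_as` (re-admit a queued record under a given name), `remove`
and `add` (an externally documented voucher, optionally with
reviewer-supplied traits, since an added species may be absent from the
backbone entirely).

## Annotation and the priority rule

Vegetation types collapse to a binary forest/grassland classification (plus
`both` and `no_info`) through an editable label map; the shipped map covers
the common Atlantic-Forest labels (ombrophilous and seasonal forest types to
forest; high-altitude grasslands, rocky fields and inselbergs to grassland).
The coarse binary is intentional: finer labels are too inconsistently
recorded to classify reliably.

Life form uses the majority rule: a single backbone form wins outright;
among several, the most frequent form observed on the species' own records
(restricted to the backbone's set) decides; frequency ties and missing
evidence fall back on a fixed precedence, tree > shrub > subshrub > liana >
herb. The precedence is an explicit stand-in for otherwise undefined tie
behaviour — it prefers the taller, more conspicuous habit, and it is
configurable.

Origin is native/non-native with cultivated and naturalised entries counting
as non-native; endemism and origin copy from the backbone; the threat
category joins from the assessment table with `NE` (not evaluated) for
absent species — the annotation never invents a category.

A species is a **conservation priority** iff it has exactly one retained
record, that record is dated and old, and the category is CR, EN, VU or DD.
Two boundary decisions are explicit:

* *Cutoff semantics*: old means `year <= cutoff_year` with default 1969. The
  half-century convention leaves the boundary year itself ambiguous; `<=` is
  the conservative (priority-friendly) reading, and `cutoff_year` is a
  parameter, so the alternative reading is one flag away.
* A species whose only record is undated is *not* a priority: the rule
  requires positive evidence of an old collection, and an unknown year is
  not that.

## Summaries and rounding

Richness counts distinct species, genera (first token of the accepted
binomial) and families *of the accepted names* — family assignment comes
from the backbone, not the verbatim record field, so synonymised records
aggregate under one family. Composition tables report counts, unrounded
shares (which always sum to 100%) and a rounded `pct` column using half-up
rounding at configurable precision, because published tables mix integer and
one-decimal percentages and R's own `round()` is banker's. Collector
rankings sort descending with alphabetical tie order and report missing
collectors as an explicit `UNKNOWN` row; temporal profiles tally records per
observed year with undated records counted apart, and the peak year takes
the earliest year on ties.

Dates are parsed by scanning for the first four-digit token between 1750 and
the current year, which uniformly covers ISO-8601 full and partial dates,
day-first dates and bare years; anything else (two-digit years, "s.d.")
yields an absent year that is counted, not guessed.

## The synthetic generator

`generate_flora()` emulates the data a protected-area curation project
starts from. Under a single seeded random stream consumed in a fixed stage
order (so a config is reproducible to the byte), it synthesises:

* a backbone of pronounceable but non-existent names — genus and epithet
  pools are built under a minimum pairwise edit distance of 3, which
  guarantees that a planted one-edit misspelling is strictly closest to its
  true name, keeping resolution ground truth unambiguous;
* per-species traits, an assessment table, and a configurable number of
  species forced to satisfy the priority rule (one clean record, old year,
  eligible category);
* an occurrence table with a right-skewed records-per-species distribution,
  a skewed collector pool with per-collector sequential numbers (so no
  accidental key collisions), mixed date dialects, and planted corruption:
  duplicate twins (exact key sharers with a different barcode and collection
  code), one-edit misspellings, synonym usage, out-of-area localities,
  genus-level determinations, missing years and collectors. Corruption
  classes are disjoint per record and twins are planted only on otherwise
  clean records, so each planted defect maps to exactly one cleaning stage
  and the truth manifest's per-stage counts are exact.

The default configuration is a mid-sized study: 800 species (680
angiosperms, 7 gymnosperms, 113 lycophytes and ferns), 60 families, 290
genera, 5,000 gatherings, duplicate rate 0.10, misspelling rate 0.05 at one
edit, out-of-area rate 0.02, undetermined rate 0.05, 1% missing years and
collectors, collection years 1871–2015 with 75% recent and a weighted peak
year, and 12 forced priority species. Tests use smaller instances of the
same generator (50–75 species, 200–500 records) where the full size adds
nothing to the property being checked.

`verify_recovery()` compares a pipeline run against the manifest on ten
exact checks: species set, per-group richness, the three per-stage removal
counts, per-record resolution outcomes, per-species temporal statuses, the
priority set, collector counts and the peak year.

**What passing recovery does and does not show.** The generator plants
defects that are *in-model*: misspellings within the matcher's budget, exact
key-sharing duplicates, localities drawn from known include/exclude pools.
Real exports contain out-of-model noise — collector-name variants that defeat
the three-part key, digitisation errors in locality strings that match no
gazetteer term, misspellings beyond one edit, genuinely ambiguous names.
Recovery passing shows the pipeline implements its stated rules exactly; it
does not show those rules capture everything a taxonomist would. That gap is
precisely why the review queues exist, and on real data the queue sizes are
the quantity to watch.

## Degenerate inputs and numerical choices

Empty tables flow through every stage (empty ledger stages with zero
inputs); an empty checklist is refused at write time. Duplicate barcodes
within a source file and referentially broken backbones (a synonym pointing
at a synonym, duplicate name rows) are hard errors at load time, not
warnings. Coordinates are validated to their legal ranges and otherwise
stored verbatim; they are never used for filtering. All text comparison
folds case and accents via ICU transliteration; stored values keep their
accents. Edit distances are plain Levenshtein (`utils::adist`), unit costs.

## Known limitations

* The three-part duplicate key cannot see duplicates with divergent
  collector transcriptions or missing fields; such sheets remain as separate
  records (over-counting) rather than being probabilistically linked.
* Locality screening is substring-based; it cannot resolve places whose
  names legitimately contain an include term, beyond the word-boundary rule
  and the review queue.
* Fuzzy matching at budget 1 will not catch two-edit misspellings; raising
  the budget raises the ambiguity rate, and the right trade-off depends on
  the density of the backbone.
* The generator does not model collector-effort correlation, spatially
  explicit localities or realistic name statistics; it is a correctness
  instrument, not an ecological simulator.
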