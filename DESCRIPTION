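Package: herbcat
Title: Herbarium Occurrence Cleaning and Protected-Area Plant Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline that turns raw herbarium occurrence
    records into a vascular-plant catalogue for a protected area: reading and
    writing Darwin Core occurrence tables, cleaning (species-level
    determination, locality screening against a gazetteer, duplicate removal
    on the collector/number/year key) with a full per-stage ledger, taxonomic
    name resolution against a backbone of accepted names and synonyms with
    orthographic (edit-distance) matching, per-species trait and threat
    annotation, conservation-priority flagging, and catalogue summary
    statistics. Includes a synthetic-data generator with a machine-readable
    truth manifest so every stage is testable and parameter-recoverable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    stringi,
    rlang,
    ggplot2,
    generics,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
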