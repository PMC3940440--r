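Package: taxatext
Title: Dictionary Annotation and Species Association Networks from Taxon Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines the narrative text attached to taxon pages in biodiversity
    aggregators. One workflow tags text objects with concept URIs by lowercase
    substring search over a stem-keyed dictionary; a second locates scientific
    names in ecology-subchapter text, reconciles synonyms against a names
    table, and assembles a directed species association network for export to
    graph tools. Includes a full evaluation harness (per-unit and micro
    precision/recall/F1 confusion tables, Fleiss' kappa, relative improvement,
    error-category reporting) and a seeded synthetic-corpus generator that
    plants gold annotations, gold associations, and the documented
    false-positive modes (negation, related taxa, word parts, generalities,
    homonyms) at configurable rates, so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stringi,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
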