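Package: ontoprofile
Title: Category Composition Profiling of the Human Phenotype Ontology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to profile the composition of the Human Phenotype
    Ontology (HPO) by organ-system category. Parses ontologies from OBO
    flat files or a two-table spreadsheet dialect, extracts the leaf terms
    of every category directly under a chosen root (by default Phenotypic
    abnormality, HP:0000118), merges clinician curation tables that tag
    each term with up to four attributes (Disease Name, Condition, Test
    Data, Symptoms and Findings), and computes per-category count and
    percentage reports. A seeded synthetic-ontology generator with
    recorded ground truth makes every stage testable without downloading
    HPO.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
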