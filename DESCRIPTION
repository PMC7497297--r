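Package: mzannotate
Title: Metabolite Annotation of Accurate m/z Values via Adduct and Isotope
    Expanded Compound Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for putative metabolite annotation in untargeted
    (direct-infusion) mass spectrometry. Expands compound tables into the
    theoretical m/z values of their common adducts and isotopologues, stores
    the expanded records in an indexed local database, and annotates measured
    m/z values by ppm-tolerance search with isotope filtering and ppm-error
    ranking. Where no database hit exists, candidate molecular formulas are
    enumerated by branch-and-bound decomposition under Seven-Golden-Rules
    style constraints (element ranges, ring-plus-double-bond validity,
    element ratios). A minimal statistics layer (normalization, imputation,
    Welch t-tests with false-discovery-rate control, fold changes,
    hypergeometric overlap tests) connects peak tables and sample metadata to
    the annotation step, and seeded synthetic-data generators make the whole
    workflow testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    parallel,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
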