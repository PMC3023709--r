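Package: protfun
Title: Multi-Label Protein Function Prediction from Weighted Interaction
    Networks and Sequence Hybrid Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts multi-label protein functional categories (the 24
    top-level FunCat classes) by two complementary routes: a
    guilt-by-association scorer on weighted protein-protein interaction
    networks (the "inclined potential", a per-category sum of interaction
    confidence weights to annotated neighbours) and a sequence-based
    nearest-neighbour predictor built on 132 hybrid
    composition-transition-distribution (CTD) and amino-acid-composition
    descriptors, with mRMR feature ranking and incremental feature
    selection. Includes multi-order jackknife evaluation statistics
    (per-order accuracy, mean function count, top-k coverage), seeded
    synthetic-data generators for annotated homophilous networks and
    planted-feature tables, and readers/writers for FASTA, edge-list and
    annotation formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
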