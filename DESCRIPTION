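Package: driverprox
Title: Network Proximity to Homeostatic-Process Gene Sets for Cancer
    Driver Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds consensus gene sets for conserved homeostatic processes
    (stress response, wound healing, regeneration) from per-experiment
    differential-expression tables, quantifies the network proximity of genes
    to those sets in a protein-protein interaction graph against
    degree-matched null models, and trains a cross-validated classifier on
    nine proximity fractions to prioritize cancer driver genes genome-wide.
    Includes overlap-enrichment machinery (Fisher's exact test with
    Benjamini-Hochberg adjustment), ranked-table filters, DeLong comparison
    of correlated ROC curves, fractional characterization of candidate
    lists, and a seeded synthetic-benchmark generator with planted driver
    modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ranger,
    e1071,
    xgboost,
    glmnet,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
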