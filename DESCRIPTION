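Package: EventPipe
Title: Configurable and Adaptable Biomedical Event Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A configurable pipeline for extracting typed, nested biomedical
    events from text annotated in the BioNLP shared-task standoff format.
    Four linear support-vector-machine detectors (trigger/entity, argument,
    multi-argument, hedge) are steered by a plain-text task configuration
    that lists type inventories and generalisation rules, so the system can
    be moved between annotation schemes without code changes. Three training
    objectives remove per-task hyper-parameter tuning: positive-instance
    weighting against class imbalance, covariate-shift importance weighting
    via density-ratio estimation with a rescaled loss constant, and their
    combination. Includes a standoff reader/writer, hashed sparse feature
    extraction with group-wise normalisation, a soft-boundary and partial
    recursive matching scorer with an approximate randomisation test, and a
    synthetic standoff-corpus generator for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
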