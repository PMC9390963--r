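Package: onoffgrn
Title: Dynamic Interferon Kinetics and Regulatory Network Analysis for
    Checkpoint-Blockade Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-course tumour transcriptomics under
    immune checkpoint blockade. Provides fuzzy c-means clustering of expression
    dynamics, tree-ensemble gene regulatory network inference with
    promoter-window pruning of direct transcription-factor connections,
    derivation and scoring of a fast-on/off interferon-stimulated gene
    signature, signature-matrix deconvolution of cytokine-induced states,
    a transcriptional-momentum statistic for embedding velocities,
    deterministic tumour growth-curve response classification, log-rank power
    simulation, and a synthetic-data generator with embedded regulatory ground
    truth that emulates a two-model, four-timepoint, responder/non-responder
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    pracma,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
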