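Package: cas13design
Title: Cas13d Guide Efficiency Modelling, Screen Analysis and Guide Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and scoring CRISPR-Cas13d guide RNAs and for
    analysing pooled Cas13d proliferation screens. Implements tiling guide
    design with cloning-site and uniqueness filters, RNA secondary-structure
    folding (a ViennaRNA wrapper plus an internal maximum-pairing fallback),
    sigmoid normalisation of guide log-fold-changes, a two-branch
    convolutional-recurrent network that scores on-target efficiency from
    guide sequence and predicted structure, curated-feature classical
    baselines, Integrated-Gradients attribution, an off-target viability
    model built from non-essential-gene guides, control-aware count
    normalisation with a permutation-based negative-selection test, and a
    synthetic screen simulator with planted sequence and structure signal so
    the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    generics,
    ggplot2,
    randomForest,
    xgboost,
    e1071,
    rpart,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
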