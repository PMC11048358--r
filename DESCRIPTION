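Package: pseustack
Title: Stacked Ensemble Prediction of RNA Pseudouridine Sites with
    Particle-Swarm-Weighted RNA Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrainable predictor for pseudouridine (PseU) sites in
    fixed-length RNA windows centered on a uridine. Sequences are encoded
    with one-hot and k-mer frequency representations (k = 1, 2, 3), five
    tree-ensemble base classifiers (AdaBoost, gradient boosting, extreme
    gradient boosting, random forest, extra trees) are trained per encoding
    with an importance-threshold feature-selection sweep, and their
    out-of-fold positive-class probabilities form a 30-dimensional RNA
    profile per sequence. Particle swarm optimization searches per-dimension
    profile weights that maximize the cross-validated accuracy of a logistic
    meta-classifier, which produces the final site call. Includes FASTA
    input/output, a synthetic motif-enriched window generator, evaluation
    metrics (ACC, SN, SP, MCC), cross-validation harnesses, diagnostics and
    plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
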