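Package: tnbcscm
Title: Set Covering Machine Analysis of Triple-Negative Breast Cancer Multi-Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes separating triple-negative breast cancer (TNBC)
    from other breast cancer subtypes with interpretable rule-based machine
    learning. Provides a from-scratch Set Covering Machine (a greedy learner of
    sparse conjunctions of single-attribute threshold rules), multi-omics view
    assembly with methylation platform fusion and label-conditional imputation,
    a repeated stratified train/test protocol with decision-tree and
    random-forest baselines, feature counting over the best models with
    direction-of-regulation calls, a synthetic multi-omics cohort generator
    with planted discriminative genes for validation, and a filtering chain for
    AP-MS/BioID protein-interaction score tables (Bayesian false discovery rate
    and contaminant-frequency cut-offs with overlap classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rpart,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
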