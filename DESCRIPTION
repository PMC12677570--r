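Package: regionboost
Title: Informative Genomic Region Selection for Tumor Tissue-of-Origin
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the tissue or cell of origin of tumors from somatic
    mutation density profiles binned into fixed 1 Mbp autosomal windows.
    Provides a window catalogue builder with mappability/GC/exclusion
    filters, per-sample density and chromatin-signal profiling, a
    multiclass gradient-boosting classifier built on symmetric (oblivious)
    decision trees with ordered target encoding and grid-search tuning,
    and a resampling-based informative-region selection procedure that
    scores each window by Fisher's exact test with Benjamini-Hochberg
    false-discovery-rate control over random-subset classification trials.
    Includes a seeded synthetic cohort simulator with planted regional
    signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xgboost
Config/testthat/edition: 3
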