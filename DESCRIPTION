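Package: otumarker
Title: Metabolite-Based Prediction of Microbial Taxon Presence in Soil
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Links soil metabolite profiles to microbial community membership
    under contrasting moisture regimes. Provides preprocessing for paired 16S
    rRNA OTU count tables and GC-MS metabolite abundance matrices (rare-feature
    filtering, Jaccard-distance randomization tests for sample outliers,
    upper-quartile count normalization, log2 transformation, half-minimum
    imputation, per-sample median centering), per-metabolite mixed-effects
    treatment tests with single-step contrast adjustment, a random-forest
    classifier with out-of-bag validation and mean-decrease-Gini variable
    importance for per-OTU presence/absence prediction, and a biomarker
    ranking that pools importance scores across models passing a balanced
    accuracy gate. A synthetic data generator with planted metabolite-OTU
    associations supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    multcomp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
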