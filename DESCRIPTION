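Package: riskseq
Title: Sequence Models and Relative-Contribution Statistics for Longitudinal EHR Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds case/control cohorts from longitudinal electronic-medical-record
    style event tables with encounter-level augmentation, encodes multimodal clinical
    codes (diagnoses, medications, flagged lab results, individual and neighborhood
    social determinants of health) into visit sequences, trains recurrent sequence
    classifiers (a tanh-gated LSTM and a two-RNN reverse-time attention model) to
    predict adverse events within a 90-day window, and screens risk and protective
    factors with a perturbation-based relative-contribution statistic carrying
    delta-method confidence intervals, z-tests, and Bonferroni/FDR multiple-testing
    correction. A seeded synthetic-EHR generator with planted multiplicative effects
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
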