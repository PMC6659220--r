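Package: gatekeepr
Title: Detection of Item Pre-Knowledge with a Gated Item Response Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multiple-choice examinations in which a subset of items
    has leaked to a subset of examinees, fits a deterministic gated mixture of
    two one-parameter logistic item response models by Markov chain Monte
    Carlo, and classifies examinees as having item pre-knowledge from their
    posterior cheater probability. Includes entropy-optimal cut-off selection,
    confusion-matrix performance metrics aggregated over simulation
    replicates, conversion of apparent prevalence to true prevalence by
    closed-form inversion and by a Bayesian grid posterior, and classical test
    theory and marginal-maximum-likelihood 1-PL/2-PL psychometric summaries
    with AIC/BIC/CHull model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
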