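Package: oralsuccession
Title: Longitudinal Acquisition and Succession Analysis of the Infant Oral
    Microbiome
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing how the oral microbial community is
    acquired over the first year of life from longitudinal mother-child 16S
    rRNA gene count tables. Implements double-rarefaction core-membership
    determination with empirical inclusion probabilities, interval-pooled
    prevalence matrices and succession (acquisition-order) calls,
    Bray-Curtis ordination with permutational multivariate analysis of
    variance, convergence-over-time analysis via linear mixed models on
    ordination distances, paired pre/post life-event comparisons (solid
    food introduction, tooth eruption), and a Dirichlet-multinomial cohort
    simulator with planted ground truth for validating every analysis
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vegan,
    lme4,
    lmerTest,
    sandwich,
    lmtest,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    optparse,
    yaml
Config/testthat/edition: 3
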