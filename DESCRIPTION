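Package: gutfit
Title: Gut Microbiome Structure and Metabolic Adaptation to Exercise Training
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, tested pipeline linking the response to moderate
    aerobic exercise training with gut-microbiome community structure and
    metabolic adaptation. Implements indirect-calorimetry resting metabolic
    rate (Weir equation over the final window of a whole-room trace),
    doubly-labeled-water total daily energy expenditure (isotope dilution
    spaces, two-point elimination kinetics, fixed respiratory quotient),
    body-composition responder classification, alpha and beta taxonomic
    diversity (Shannon, Faith's PD, Bray-Curtis, weighted UniFrac, PCoA,
    PERMANOVA, beta-dispersion), a repeated stratified k-fold cross-validated
    univariate AUROC biomarker screen with exact Mann-Whitney p-values and
    bootstrap confidence intervals, and diversity-adaptation association
    statistics. A synthetic cohort generator plants configurable effects
    (predictive species, group dispersion differences, diversity-adaptation
    correlations) so that every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
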