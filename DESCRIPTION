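Package: panelscreen
Title: Strain-Panel Screening of Diet-by-Genotype Effects in Longitudinal
    Aging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for longitudinal dietary-intervention
    studies in inbred strain panels: a synthetic-cohort generator that
    reproduces the strain x sex x diet design with correlated strain
    intercepts and diet slopes; restricted-maximum-likelihood mixed models
    with kinship-scaled strain effects; broad- and narrow-sense
    heritability with profile and bootstrap confidence intervals; lifespan
    analysis (Kaplan-Meier, log-rank, stratified Cox, restricted mean
    survival time, coefficient-of-variation comparison); a per-phenotype
    genotype-by-treatment screen with empirical-Bayes strain diet-effect
    scores, clustering and model-strain selection; body-weight and frailty
    trajectory quantification on the proportion-of-life-lived scale;
    a longevity-biomarker regression screen; and penalized-spline additive
    models for late-life thermoregulatory decline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    survival,
    mgcv,
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
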