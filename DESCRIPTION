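Package: socioclock
Title: Social Network Metrics, Epigenetic Clocks and Mixed-Model Inference for Longitudinal Wildlife Cohorts
Version: 0.1.0
Authors@R: person("socioclock", "developers", role = c("aut", "cre"), email = "dev@socioclock.org")
Description: Links social bonds to biological ageing in long-term study
    populations. Computes Simple Ratio Index association networks,
    normalized node strength and male group size from field survey data;
    builds a species-specific epigenetic clock by elastic-net regression
    with leave-one-individual-out cross-validation; and relates social
    predictors to epigenetic age with crossed-random-intercept linear
    mixed models, AIC model selection, Satterthwaite p-values and
    quasi-Bayesian mediation analysis. Ships a synthetic-cohort generator
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
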