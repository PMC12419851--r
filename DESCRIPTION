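Package: agingnet
Title: Additive Bayesian Networks Linking Biological Aging Biomarkers to Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for studying how telomere length
    and DNA-methylation age-acceleration metrics relate to all-cause mortality.
    Provides seeded synthetic cohort generation from a structural model with a
    Weibull proportional-hazards mortality node, person-period discrete-time
    encoding, exact most-probable-DAG structure learning for additive Bayesian
    networks over mixed Gaussian/binomial nodes under tier and arc constraints,
    node-wise path-model estimation with survey weights and cluster-robust
    errors, indirect (mediation) effects, and the classical companion analyses:
    weighted Kaplan-Meier curves with log-rank tests, Pearson correlation
    matrices, Cox proportional-hazards models with Schoenfeld diagnostics and
    Harrell's C, and LASSO selection with forced exogenous covariates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    sandwich,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
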