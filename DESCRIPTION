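Package: rnmsom
Title: Hierarchical Multispecies Royle-Nichols Models for Camera-Trap
    Hunting Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hierarchical multispecies Royle-Nichols abundance/detection
    models to camera-trap detection histories by purpose-built Markov chain
    Monte Carlo, with Dorazio-Royle data augmentation for undetected species
    and community-level hyperparameters. Includes a synthetic-community
    generator matching the model's probabilistic structure, occasion-binned
    detection-history construction from timestamped records, posterior
    site-level richness, aggregated abundance and biomass, a conjugate Gibbs
    sampler for Bayesian Gaussian linear mixed models relating those summaries
    to hunting-management covariates, and Gelman-Rubin convergence
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
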