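Package: beakrates
Title: Rate Heterogeneity in Avian Beak-Shape Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying heterogeneity in rates of
    multivariate trait (beak-shape) evolution across a phylogeny. Provides
    quality control and averaging of crowd-sourced 3D landmark markups,
    generalized Procrustes alignment with bending-energy sliding of
    semi-landmarks, ordinary and phylogenetic principal component trait
    spaces, a reversible-jump MCMC variable-rates Brownian-motion model with
    branch and clade rate scalars, maximum-likelihood relative clade rates,
    MCMC convergence diagnostics, and species- and clade-level correlates of
    evolutionary rates via phylogenetic generalized least squares with
    Pagel's lambda. A synthetic-data module generates trees, rate-shifted
    traits, noisy multi-user markups, predictor tables and gridded ranges
    with known ground truth so every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
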