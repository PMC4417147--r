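Package: chromoem
Title: Bayesian Ensemble Inference of 3D Chromatin Structure from 3C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers an ensemble of weighted 3D chromatin conformations from
    chromosome-conformation-capture (3C/Hi-C) interaction-frequency matrices
    at restriction-fragment resolution. A bead-spring polymer conformational
    energy (harmonic stretching, worm-like-chain bending and a purely
    repulsive truncated Lennard-Jones excluded volume) serves as a Boltzmann
    prior; interaction frequencies are converted to target spatial distances
    through a power law and compared to back-computed distances under a
    Gaussian noise model. An expectation-maximization algorithm alternates
    gradient-ascent refinement and re-weighting of the ensemble members with
    a grid search over the frequency-to-distance exponent and the noise
    level. Includes Brownian-dynamics initialization, k-fold cross-validation,
    Kabsch superposition of ensemble members, locus-pair distance queries,
    contact counting and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
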