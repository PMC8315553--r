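Package: hopfbrain
Title: Whole-Brain Hopf Network Models of Brain States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and empirical fitting of whole-brain networks of
    Stuart-Landau (Hopf normal form) oscillators coupled by a structural
    connectome. Provides stochastic Euler-Maruyama integration of regional
    BOLD-like dynamics with optional homotopic periodic forcing, a
    functional-connectivity observation pipeline (band-pass filtering,
    z-scoring, Pearson correlation, Fisher-z group averaging, SSIM goodness
    of fit), genetic-algorithm estimation of regional bifurcation parameters
    under resting-state-network priors, an in-silico perturbation protocol
    yielding normalized transition scores, transition graphs and stability
    indices for brain states, and descriptive distance metrics between
    states (connectivity-correlation distance, random-forest transfer
    classification distance, model-parameter distance), plus a synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    randomForest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
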