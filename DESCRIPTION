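Package: gaitmet
Title: Biomechanical Drivers of the Metabolic Cost of Walking with a
    Powered Ankle-Foot Prosthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking multimodal gait biomechanics to the
    net metabolic rate of treadmill walking with a powered ankle-foot
    prosthesis. Provides a synthetic gait-trial generator with known ground
    truth (ground reaction forces, heel-marker trajectories, surface EMG,
    breath-gas exchange), gait event detection and individual-limb
    step-to-step transition work, EMG envelope and net metabolic rate
    processing, construction of a trial-by-feature table with baseline
    z-scoring and random-forest imputation, a Bayesian additive regression
    tree (BART) ensemble fitted by Metropolis-within-Gibbs backfitting with
    cross-validated hyperparameters, variable-inclusion-proportion (VIP)
    feature selection, and bootstrapped accumulated-local-effects (ALE)
    effect-size ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    ranger,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
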