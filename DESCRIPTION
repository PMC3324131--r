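Package: slgeno
Title: Super Learner Ensembles for Genotype-Based Prediction of
    Virologic Response
Version: 0.1.0
Authors@R:
    person("Jaguar", "Analyst", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cross-validated Super Learner analysis of HIV-1
    genotype-to-virologic-response prediction at clinical-trial scale
    (around one hundred patients, ten resistance mutations). Provides
    mutation calling against a reference amino-acid sequence, six
    candidate learners (main-effects and two-way-interaction least
    squares, a regression tree, a bagged random forest,
    deletion/substitution/addition polynomial search, and logic
    regression by simulated annealing) behind one
    fit/predict/selected-features contract, k-fold cross-validated risk
    under squared-error and one-minus-correlation losses, discrete and
    weighted Super Learner construction on the level-one prediction
    matrix, full-dataset evaluation (squared error, 1-R, R-squared,
    responder-classification accuracy), and a calibrated synthetic-data
    generator emulating the trial's marginal structure so every stage
    is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    quadprog
Suggests:
    Biostrings,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
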