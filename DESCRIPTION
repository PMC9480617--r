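Package: swaytrait
Title: Estimating Trait Measures from Postural Sway Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling self-reported psychological trait measures
    from quiet-standing center-of-pressure (CoP) recordings. Implements the
    full posturographic modelling chain: CoP ingestion from four-sensor force
    platform frames, zero-phase Butterworth preprocessing, extraction of the
    16 individual-specific postural features (sway-density statistics, Gamma
    crossing-duration parameters, path/velocity measures, spectral power),
    cross-term candidate construction, Orthogonal Forward Regression variable
    ranking with random-probe selection, training of linear, logistic and
    single-hidden-layer neural network models with multi-restart optimisation,
    Jacobian-rank overfitting screening, leave-one-out complexity selection,
    and baseline-referenced evaluation (RMSE, correlation, accuracy, ROC/AUC).
    A synthetic-cohort generator with planted cross-term effects makes the
    whole chain testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    MASS,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
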