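Package: tsto
Title: Two-Stage Taguchi Optimization for Model Hyperparameter Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of two-stage Taguchi optimization (TSTO)
    experiments for tuning hyperparameters of black-box predictive models.
    Provides a catalog of standard orthogonal arrays with orthogonality
    verification, signal-to-noise ratios (nominal-, smaller- and
    larger-the-better), main-effects response tables, pooled ANOVA with
    F-tests, additive predictions with confirmation confidence intervals,
    and a driver that screens factors on a coarse array, refines the
    numeric factors around the stage-1 winner, and validates the final
    setting with confirmation runs. Includes replay, synthetic-additive
    and multilayer-perceptron objectives, a synthetic generator for
    cardiovascular-disease-style tabular data, and a worked example of
    tuning a neural-network risk classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
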