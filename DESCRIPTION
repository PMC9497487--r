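Package: pliv
Title: Piecewise Linear Instrumental Variable Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and inference for piecewise linear instrumental
    variable (PLIV) models, in which both the instrument-to-exposure and the
    exposure-to-outcome relationships are continuous piecewise linear
    functions built from ReLU (hinge) threshold terms. Coefficients and
    threshold locations are estimated simultaneously by limited information
    maximum likelihood under bivariate normal errors, initialized by
    two-stage least squares. Provides model-based and robust sandwich
    variance estimators (with kernel density correction for the threshold
    parameters), AIC/BIC selection of the number of thresholds, scenario
    generators and a Monte Carlo harness for bias, standard error and
    coverage studies, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
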