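Package: psdeg
Title: Predictive Models of Phytosterol Degradation in Stored Rapeseed
Version: 0.1.0
Authors@R:
    person("psdeg", "maintainers", email = "psdeg@example.org", role = c("aut", "cre"))
Description: Tools for modelling the degradation kinetics of total phytosterols
    in bulk-stored rapeseed as a function of seed water activity, temperature
    and storage time. Provides a synthetic storage-experiment generator that
    emulates a 16-condition factorial design with triplicate sampling, a
    second-order response-surface regression stage (with the published
    reference coefficient set), small from-scratch multilayer-perceptron and
    radial-basis-function network regressors with topology grid search and
    weighted-error model selection, a predictive-model validation suite
    (R-squared, MAE, RMSE, MRPE, bias factor, MAPE, accuracy factor) including
    the elliptical joint confidence region (EJCR) test, and an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
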