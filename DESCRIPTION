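Package: dkimplant
Title: Empirical Release Models for Reservoir-Style Polymer Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling membrane-controlled drug release from
    reservoir-style poly(epsilon-caprolactone) implants. Implements the
    Fickian zero-order release model for a saturated reservoir, estimation
    of the lumped diffusion-partition parameter Dk from cumulative-release
    curves, inverse design of membrane wall thickness for a target release
    rate, a quantitative structure-property (QSPR) regression workflow that
    predicts log10(Dk) from drug physicochemical properties (with transform
    search and Wald-test backward elimination), support-vector and
    random-forest comparators, evaluation metrics (MSE and log-fold coverage
    bands), and synthetic-data generators with known ground truth covering
    zero-order, burst, and reservoir-depletion release regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
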