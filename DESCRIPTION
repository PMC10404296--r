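Package: seeaflux
Title: National Forest Carbon-Flux Mapping and UNSEEA Carbon Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps net above-ground forest carbon flux over an accounting
    period from reference plots and covariate rasters using a stacked
    ensemble of machine-learning regressors with quantile-regression-forest
    prediction intervals, screens the covariate feature space for areas
    unsupported by the reference sample, aggregates per-pixel map errors to
    ecosystem-class standard deviations with variogram-based spatial
    correlation models, and compiles UN System of Environmental-Economic
    Accounting (UNSEEA) opening/flux/closing carbon accounting tables.
    Includes a synthetic-landscape generator so the full pipeline can be
    exercised and validated on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    xgboost,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
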