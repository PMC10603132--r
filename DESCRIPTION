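Package: fireCausal
Title: Lagged Causal Attribution of Wildfire Burned Area
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage lagged causal discovery and dominance attribution for
    wildfire activity. Implements PC-style condition selection followed by
    momentary conditional independence (MCI) testing with linear partial
    correlation on detrended, deseasonalized weekly anomaly panels; climate
    zone by vegetation type (ecoregion) stratification of gridded fields;
    attribution of burned area to top-down weather versus bottom-up fuel
    precursor groups (dominant precursor, predictability score, sign
    fractions, correlation-weighted time lags, covariate-binned dominance
    profiles); and a synthetic vector-autoregression generator with planted
    causal structure, seasonality, trend, and zero-inflated skewed burned-area
    marginals that provides a ground-truth test surface for the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'fireCausal-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'pcor.R'
    'pcmci.R'
    'attribution.R'
    'scenario.R'
    'simulate.R'
    'calibration.R'
    'ecoregion.R'
    'preprocess.R'
    'scene.R'
    'pipeline.R'
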