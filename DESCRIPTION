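Package: seasonalSDM
Title: Seasonally Dynamic Presence-Only Ensemble Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for seasonally dynamic, sex-stratified, presence-only
    species distribution modeling on 1-km equal-area raster grids, built around
    the workflow used for continental-scale migratory bat analyses. Covers
    occurrence-record quality control and seasonal/sex stratification,
    construction and correlation screening of seasonal climate and land-cover
    predictor stacks, five presence-background model forms (logistic GLM, MARS,
    boosted regression trees, random forest, and a native Maxent-style
    penalized exponential model) under 10-fold cross-validation,
    threshold-dependent evaluation at the minimum-training-presence threshold,
    permutation delta-AUC variable importance, binary ensemble mapping, and
    point-exposure summaries at wind-turbine locations. A synthetic-landscape
    generator with spatially autocorrelated covariates and a known logistic
    suitability surface makes the entire pipeline testable without external
    data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet,
    ranger,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
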