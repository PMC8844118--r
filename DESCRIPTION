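Package: hsmismatch
Title: Virtual-Ecologist Analysis of Climate-Dataset Version Mismatch in
    Habitat Suitability Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates virtual species over paired synthetic climate-surface
    versions and quantifies how habitat-suitability-model predictions diverge
    between the two versions as a function of species niche type, grid
    resolution and projection scenario. Provides a seeded synthetic-climate
    generator with spatial autocorrelation and resolution/scenario variants,
    virtual-species simulation (response-curve and PCA-niche suitability,
    logistic conversion to occurrence probability, imperfect-detection
    sampling), residual Moran's I correlograms with checkerboard spatial-block
    cross-validation, four habitat-suitability learners with AUC/TSS gating
    and AUC-weighted ensembles, permutation variable importance, projection
    mismatch diagnostics, and random-forest factor-importance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
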