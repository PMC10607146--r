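Package: vectorshift
Title: Niche and Range Shift Analysis for Invasive Disease Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify niche and range shifts between native and
    introduced populations of invasive species, with the mosquito vectors
    Aedes aegypti and Ae. albopictus as the motivating use case. Implements
    occurrence record cleaning and spatial rarefaction, computation of the 19
    bioclimatic variables from monthly climate grids, permutation-importance
    guided pruning of collinear predictors, TSS-weighted ensemble species
    distribution models with pseudo-absence sampling and null-model
    evaluation, COUE niche dynamics (expansion, stability, unfilling) in
    kernel-smoothed PCA environmental space with Schoener's D and
    equivalency/similarity permutation tests, breadth-ratio and
    niche-similarity indices, and latitude-weighted range decomposition with
    range-ratio and range-similarity indices. A virtual-species simulator
    with known niche geometry supports end-to-end validation by parameter
    recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere,
    pracma,
    MASS,
    rpart,
    nnet,
    randomForest,
    glmnet,
    xgboost,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
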