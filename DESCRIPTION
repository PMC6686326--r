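Package: hybridsdm
Title: Habitat Suitability Modeling of Tree Importance Values on a
    Density-Adaptive Hybrid Lattice
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models tree species habitat suitability from forest inventory
    plots on a two-resolution ("hybrid") lattice in which 20-km cells are
    subdivided into four 10-km cells wherever plot density supports the finer
    grain.  Plot-level species importance values (0-100, combining relative
    stem density and relative basal-area dominance) are aggregated to cells,
    filtered, and modeled with random forests (1,001 trees); per-tree
    predictions feed a mean-median combination rule that zeroes unstable
    low-suitability cells, together with per-cell confidence values.  Model
    quality is summarized by a five-component reliability score (out-of-bag
    pseudo-R2, fuzzy kappa, true skill statistic, bagging deviance stability,
    and top-five predictor stability), species range codes, and a
    cross-species predictor importance index.  A synthetic-landscape generator
    with known ground truth supports end-to-end testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
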