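Package: bioscen
Title: Uncertainty Partitioning for Ensemble Biodiversity Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and attribute uncertainty in ensemble projections
    of species distributions under climate change. Simulates a planar equal-area
    world with virtual species of known Gaussian niches, fits an ensemble of
    species distribution models (GLM, GAM, boosted trees, random forest) with
    repeated split-sample validation scored by the true skill statistic,
    projects retained models onto factorial climate scenarios (GCM x RCP x
    period) under no-dispersal and distance-limited dispersal assumptions,
    derives species-, pixel- and region-level sensitivity metrics (change and
    loss in climatic suitability, richness change, species loss, temporal and
    spatial turnover), and partitions the resulting deviance among modelling
    choices with nested and full-factorial sequential ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
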