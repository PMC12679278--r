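Package: metgge
Title: Multi-Environment Trial Analysis with GGE Biplots, Selection
    Indices and Cross-Validated Trait Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of balanced multi-environment trials
    (MET) in plant breeding: two-way ANOVA with percent contribution of
    variance sources, method-of-moments variance components, genetic
    parameters (GCV, PCV, broad-sense heritability, genetic advance),
    a multi-trait base linear phenotypic selection index, a complete GGE
    biplot engine (environment centering, singular value partitioning,
    average-environment-coordination mean-vs-stability view, ideal-genotype
    ranking, discriminativeness-vs-representativeness environment
    evaluation, which-won-where mega-environment delineation), Ward
    hierarchical clustering, and a leave-one-out cross-validation harness
    with grid search and six regression error metrics for random forest
    and multilayer perceptron trait prediction. Includes a configurable
    simulator for balanced trials with additive genotype, environment and
    interaction effects, optionally with planted crossover interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
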