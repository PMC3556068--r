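Package: xcsfqsar
Title: Piecewise-Linear QSAR Modelling with an XCSF Learning Classifier System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modelling for
    compound collections whose molecular descriptors are multimodally
    distributed, where a single global regression fits poorly. Implements an
    XCSF learning classifier system for function approximation: a population
    of hyperellipsoidal-condition rules with local linear models trained
    online by covering, recursive-least-squares or delta-rule weight updates,
    accuracy-based fitness, and a niche genetic algorithm. Includes the
    standard four-step descriptor reduction pipeline (constancy,
    target-correlation and cross-correlation filters, stepwise multiple
    linear regression) with PCA-based representative selection, K-means
    partitioning with silhouette-based choice of K feeding the covering
    stretch, MLR and feed-forward neural-network baselines, a k-fold
    cross-validation comparison harness with paired significance tests, and a
    synthetic multimodal piecewise-linear data generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
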