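Package: evoforecast
Title: Mutation Compendium Analysis and Mutation-Target Prediction for
    Adaptive Laboratory Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing compendia of mutation events from adaptive
    laboratory evolution (ALE) experiments with Escherichia coli and similar
    microbes. Provides a tabular data model for mutation events and culture
    conditions (with gene-name normalization against a genome annotation and
    binary condition encoding), Monte-Carlo hotspot significance under a
    length-proportional null, sliding-window mutation-density scans with
    gamma-fit significance thresholds, mutual-information co-occurrence
    analysis with spectral clustering, replicate-convergence statistics
    (averaged mutation frequency, global and pairwise overlap ratios and
    their dependence on replicate number), and a per-gene ensemble predictor
    (naive Bayes, RBF support vector machine, feedforward neural network) of
    mutation targets for novel culture conditions, evaluated by
    leave-one-condition-out cross-validation and bootstrap forward
    validation. A synthetic-compendium generator with planted, recoverable
    ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    e1071,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
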