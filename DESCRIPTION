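Package: rankery
Title: Analysis and Probability Modelling of Ranking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for describing, testing, visualizing and modelling complete
    ranking data in which N judges each rank the same k items. Provides
    descriptive statistics (mean ranks, pair and marginal matrices),
    chi-squared tests of uniformity and two-sample comparison tests,
    right-invariant and weighted rank distances, maximum-likelihood fitting of
    the Luce (Plackett-Luce) model, the rank-ordered logit model,
    distance-based (Mallows-type), phi-component and weighted distance-based
    models, multidimensional preference (MDPREF) biplots via the singular
    value decomposition, Analytic Hierarchy Process weights with Saaty and
    Koczkodaj inconsistency indices, local k-nearest-neighbour label ranking
    with cross-validation, and exact samplers for every model family.
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
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
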