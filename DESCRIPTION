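Package: subsetvi
Title: Variable Importance and Valid p-Values for Best Subset Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Assesses the importance of predictors (or predictor sets) under
    best subset selection with an L0-penalized Gaussian likelihood. Implements
    exact subset search (exhaustive enumeration and branch-and-bound over a
    cached cross-product matrix) for AIC, BIC, HQIC or custom penalties,
    forward/backward heuristics, the variable importance statistic VI and its
    non-negative modification mVI, naive chi-squared reference p-values, and
    parametric-bootstrap p-values that remain valid under strong predictor
    correlation. Includes a simulation toolkit for null-distribution and
    type-I-error studies with equicorrelated Gaussian designs, broom-style
    tidiers, ggplot2 visualisations, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
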