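Package: gaintwin
Title: Gain-Modulated Digital-Twin Networks for Arithmetic Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates individual differences in arithmetic learning with
    gain-modulated recurrent convolutional networks ("digital twins").
    Renders visually presented addition and subtraction problems, trains a
    four-area recurrent network whose neural excitability is a single gain
    parameter applied at every rectification, matches networks to subjects
    by normalized achievement scores, and analyses behavior (trueness,
    precision, response entropy), neural representational similarity, and
    the mean-field geometry (capacity, radius, dimensionality, center
    correlation) of result manifolds.
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
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
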