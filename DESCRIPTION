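Package: ecomoran
Title: Eco-Evolutionary Moran Dynamics with Environmental Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a finite two-species population whose birth-death (Moran)
    dynamics are coupled to a two-resource environment through positive or
    negative feedback. Provides exact and weak-selection fixation
    probabilities for the feedback-free process, a fast individual-based
    simulator for the coupled species-environment system, Monte-Carlo
    estimators of invasion and competition fixation probabilities and of
    early-stage fitness dominance, and reproducible parameter-sweep
    experiments with tabular output.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
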