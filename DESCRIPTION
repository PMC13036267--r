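Package: fvcox
Title: Functional Varying-Coefficient Cox Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits proportional-hazards models whose linear predictor combines
    scalar covariates with fixed coefficients, covariates whose coefficients
    vary smoothly with an index variable (approximated by B-splines), and a
    densely observed functional covariate entering through a functional
    coefficient (approximated by truncated functional principal component
    scores). Provides the partial-likelihood Newton solver, truncation
    selection by proportion of variance or AIC, a survival-data simulator
    based on cumulative-hazard inversion with calibrated uniform censoring,
    and a replicated Monte Carlo study driver reporting root average squared
    errors and integrated squared biases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
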