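Package: rogersfr
Title: Functional Response Analysis with Rogers' Random Predator Equation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative functional-response analysis of
    prey-depletion feeding trials. Classifies functional-response type
    from binomial logistic regression of proportion consumed on prey
    density, fits Rogers' random predator equation by maximum likelihood
    using a Lambert W closed-form solution for expected consumption,
    derives maximum feeding rates (1/h), and quantifies uncertainty with
    non-parametric bootstrap confidence intervals and per-density
    prediction bands. Includes a stochastic simulator of depletion-driven
    Type II feeding trials (binomial and event-driven mechanisms) with a
    preset matching a six-density trout-fry trial design, plus an
    end-to-end pipeline producing tabular and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
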