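Package: cannadid
Title: Difference-in-Differences Evaluation of Cannabis Legalisation on Use and
    Impaired Driving
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested analysis pipeline for quasi-experimental evaluation of
    cannabis legalisation using repeated cross-sectional surveys in an
    intervention and a control country. Implements seeded synthetic survey
    microdata generation, response-quality filtering and analytic-sample
    derivation, post-stratification weighting (cell weighting and raking) with
    Rao-Scott-corrected contingency tests, weighted logistic
    difference-in-differences models fitted by iteratively reweighted least
    squares with Wald inference, Nagelkerke R-squared and generalised variance
    inflation diagnostics, covariate screening, Monte-Carlo power analysis with
    minimum-detectable-effect search, and a bootstrap decomposition of driving
    under the influence of cannabis (DUIC) episodes into cannabis-only and
    polysubstance components by use frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    ggplot2
Config/testthat/edition: 3
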