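Package: scaaens
Title: Multi-Uncertainty Statistical Catch-at-Age Stock Assessment with
    Model Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Conditions a suite of age-structured stock states from
    length-based fisheries data under process uncertainty in growth
    (t-copula with triangle marginals on the von Bertalanffy parameters)
    and model uncertainty in natural mortality (a constant rate versus a
    length-based Gislason curve rescaled to Jensen's level), converts
    length-based catch and survey data to age-based data by deterministic
    length slicing with automatic plusgroup selection, fits a grid of
    statistical catch-at-age models (pluggable fishing-mortality,
    catchability and recruitment submodels) by maximum likelihood with
    estimation-uncertainty resampling, and integrates the resulting model
    variants by Hartigan dip-test filtering of unstable fits and
    inverse-median-GCV model averaging.  Includes an age-structured
    operating model that generates fully known synthetic length-based
    inputs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    splines,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
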