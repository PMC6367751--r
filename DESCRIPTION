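Package: spurint
Title: Spurious Interaction Induced by Categorizing Continuous Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the spurious interaction that arises when
    correlated continuous exposures are dichotomized before entering a linear
    regression model. Provides closed-form orthant probabilities and truncated
    conditional means for the standard bivariate normal at a common cut point,
    the induced coefficients of the saturated model in the two dichotomized
    exposures (including the zero-interaction condition and its numerical
    roots), point-biserial reliability diagnostics that explain the sign and
    size of the induced interaction as differential measurement error, a
    Gaussian-copula Monte Carlo engine reproducing the effect under normal,
    uniform and chi-square(2) marginals, and stratified contingency-table
    machinery demonstrating that collapsing exposure categories induces
    heterogeneity of relative risks across strata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
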