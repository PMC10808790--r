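Package: cuspfit
Title: Stochastic Cusp Catastrophe Regression with Multimodality Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the stochastic cusp catastrophe
    regression model of Cobb, in which a continuous outcome follows the
    stationary density proportional to exp(a*y + b*y^2/2 - y^4/4) and the
    asymmetry (a), bifurcation (b) and rescaled state are linear functions of
    observed variables. Includes the competing linear and logistic models,
    information-criterion and likelihood-ratio model comparison, a
    multimodality test battery (Hartigan dip test, Silverman critical-bandwidth
    test, kernel mode counting, a simplified SiZer map), and a synthetic-data
    generator that draws the state exactly from the cusp stationary density.
    Motivated by applications to survey-scale educational data such as PIRLS
    reading-engagement scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
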