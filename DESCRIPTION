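Package: pmkl
Title: Shrinkage Estimation for Poisson Regression Under Multicollinearity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Poisson regression models by iteratively reweighted least
    squares and computes shrinkage alternatives to the maximum likelihood
    estimator for collinear designs: the Poisson ridge estimator, the Poisson
    Liu estimator, the Poisson Kibria-Lukman estimator, and the Poisson
    modified Kibria-Lukman estimator. Provides the data-driven biasing
    parameter selection rules for each estimator, closed-form theoretical
    mean squared error expressions in canonical (spectral) coordinates,
    numerical matrix mean-squared-error dominance checks, collinearity and
    goodness-of-fit diagnostics, and a Monte-Carlo experiment engine for
    comparing the estimators over grids of sample size, collinearity level
    and intercept.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
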