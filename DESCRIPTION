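Package: sdeclass
Title: Optimal Bayesian Classification of Sample Paths with SDE-Induced
    Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Binary classification of multivariate Gaussian-process time
    series when prior knowledge about the dynamics is available as linear
    vector stochastic differential equations (SDEs).  Computes the
    Gaussian-process moments of linear SDEs in closed form, simulates
    sample paths by the Euler-Maruyama scheme, maps SDE-derived moments
    into a normal-inverse-Wishart prior, and implements the optimal
    Bayesian classifier alongside quadratic discriminant analysis and the
    plug-in Bayes baseline.  Includes simulation protocols for studying
    the effect of prior misspecification, among them an
    Ornstein-Uhlenbeck model of quantitative-trait evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    graphics,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
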