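Package: lrmean
Title: Log-Ratio Estimators of a Finite-Population Mean under SRSWOR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based estimation of a finite-population mean from a simple
    random sample drawn without replacement (SRSWOR), using a known auxiliary
    mean. Implements the classical mean, ratio, product, exponential-ratio,
    regression and log-auxiliary estimators together with two logarithmic
    ratio-type estimators carrying Searls-type tuning constants. First-order
    bias and mean squared error are available through two parallel paths: a
    literal transcription of the published closed forms, and an independent
    truncated bivariate Taylor-series engine in the sampling errors (e0, e1)
    with optimal-constant solvers. A Monte-Carlo framework generates correlated
    Normal, Gamma and Lognormal finite populations via a Gaussian copula,
    draws SRSWOR replicates, and reports empirical MSE and percent relative
    efficiency with Monte-Carlo standard errors and percentile confidence
    intervals, including data-driven tuning of free constants.
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
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
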