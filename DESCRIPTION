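Package: tlbhe
Title: The Topp-Leone Burr-Hatke Exponential Lifetime Distribution
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Density, distribution, quantile and random generation for the
    two-parameter Topp-Leone Burr-Hatke exponential (TL-BHE) lifetime
    distribution, together with moments, entropy and order statistics;
    seven frequentist estimators (maximum likelihood, maximum product
    spacing, least squares, weighted least squares, Cramer-von Mises,
    Anderson-Darling and right-tailed Anderson-Darling); Bayesian
    estimation by random-walk Metropolis-Hastings under squared-error,
    LINEX and generalized entropy losses; single- and multi-component
    stress-strength reliability; a right-censored log-location-scale
    (accelerated failure time) regression model; goodness-of-fit and
    information-criterion model comparison against exponential, Weibull
    and baseline Burr-Hatke exponential fits; and a Monte-Carlo study
    harness for bias, mean squared error and interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
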