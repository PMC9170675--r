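Package: evtest
Title: Full Bayesian Significance Testing of Sharp Hypotheses via the e-Value
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the Full Bayesian Significance Test (FBST) for a sharp
    (point) null hypothesis from posterior draws of a scalar parameter. The
    posterior density is estimated by a Gaussian kernel density estimator, a
    surprise function is formed against a pluggable reference function (flat,
    normal, Cauchy, half-Cauchy, Student t, or user supplied), and the
    Bayesian evidence against the null (the e-value) is obtained by numerical
    integration of the posterior over the tangential set. Also provides the
    standardized e-value based on the chi-square asymptotics of the e-value,
    asymptotic Bayesian and frequentist p-value analogues, broom-style tidiers,
    ggplot2 visualizations of the surprise function with the tangential set
    shaded, seeded synthetic-posterior generators (including a two-sample
    t-test effect-size sampler under a Cauchy prior), and a command-line
    interface reading draws from CSV and writing JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyselect,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
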