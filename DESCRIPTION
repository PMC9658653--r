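Package: bssd
Title: Bayesian Sample Size Determination for a Binomial Proportion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample size determination for a single binomial proportion using
    Bayesian average coverage, average length, and worst outcome criteria
    generalized to arbitrary unimodal priors. Priors can be conjugate Beta
    distributions discounted through a power prior, or semiparametric
    B-spline distributions elicited from expert quantiles by constrained
    quadratic programming. Includes expert-opinion pooling, highest posterior
    density interval computation for analytic and numeric posteriors,
    preposterior predictive distributions, a frequentist precision benchmark,
    and an end-to-end scenario pipeline with JSON/CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    splines,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
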