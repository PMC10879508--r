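Package: dgcm
Title: Discontinuous Growth Curve Models for Experience-Sampling Well-Being Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study daily affective well-being around a collective
    event with discontinuous growth curve models. Provides preprocessing of
    experience-sampling (EMA) data into standardized daily well-being scores,
    event-time change-parameter coding, maximum-likelihood estimation of
    random-intercept random-slope linear mixed models via a profiled grouped
    marginal likelihood, comparison of an eight-model trajectory family by
    AIC, cross-level moderation of recovery slopes by personality meta-traits,
    within-person/between-person decomposition of a daily event-salience
    series, and a synthetic-data generator that emulates the staggered
    experience-sampling design for end-to-end testing and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
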