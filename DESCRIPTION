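Package: photosens
Title: Continuous Photoperiod Sensitivity of Seed Germination
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how strongly seed germination depends on day length
    from three-treatment incubator trials (short-day 6L/18D, equal 12L/12D,
    long-day 18L/6D). Fits per-species binomial regressions with heavy-tailed
    zero-centred priors so that treatments with zero germination still yield
    finite contrasts, summarises the treatment contrasts as a continuous
    photoperiod sensitivity metric with parametric-bootstrap standard errors,
    classifies species as long-day, short-day, intermediate or insensitive,
    tests for phylogenetic signal in the metric (Pagel's lambda, Blomberg's K),
    and relates sensitivity to seed and habitat predictors with
    inverse-variance-weighted Gamma regressions. A synthetic-data generator
    produces germination trials with known true sensitivity, trait tables with
    configurable effects, and trees with Brownian-motion tip traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    phytools,
    picante,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
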