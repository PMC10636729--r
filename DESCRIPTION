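Package: maternalvar
Title: Maternal Variance Partitioning of Behaviour and Survival by
    Multi-Trait Bayesian Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gibbs-sampled multivariate generalized linear mixed models for
    partitioning variance in early-life behaviour and survival between
    mothers, individuals and residual noise, as used in studies of animal
    personality and maternal effects. Fits Gaussian traits jointly with a
    binary trait on a latent logit liability scale, with an unstructured
    mother-level covariance matrix, an optional offspring-level term, and
    selectively fixed residual elements. Includes latent-to-data-scale
    conversion of variance components for binary traits (with the binomial
    sampling variance term), repeatability decompositions, an upper-limit
    heritability from mother-offspring covariance, posterior modes, highest
    posterior density intervals and pMCMC, plus a synthetic-data generator
    that emulates the hierarchical structure of wild-population
    mother-offspring behavioural data for parameter-recovery testing.
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
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
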