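Package: pairtrend
Title: Hierarchical Spatio-Temporal Trend Models for Breeding Pair Survey Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian hierarchical spatio-temporal models for segment-level
    counts of breeding pairs from stratified aerial waterfowl surveys such as
    the North American May Breeding Pair Survey. Counts are modelled with
    negative binomial or zero-inflated negative binomial observation models
    over a log-linear process with stratum-specific intercepts and trends, a
    proper conditional autoregressive (CAR) spatial random field on stratum
    centroids, and stratum-level AR(1) temporal residuals. Includes an
    adaptive Metropolis-within-Gibbs sampler with conjugate updates for the
    field precisions, DIC model comparison across observation models and
    random-effect configurations, credible-interval trend classification per
    stratum, posterior predictive trajectories, and a synthetic-data
    generator emulating the survey design for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    coda,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
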