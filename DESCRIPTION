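Package: spatzip
Title: Spatio-Temporal Zero-Inflated Poisson Disease Mapping with CAR Random Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area analysis of infectious-disease surveillance
    counts: cumulative incidence and standardized morbidity ratios, additive
    seasonal-trend decomposition by loess, lagged climate covariate screening
    with Poisson regression and variance inflation factors, zero-inflated
    Poisson (ZIP) maximum likelihood with the Vuong test, and four nested
    Bayesian ZIP spatial models with intrinsic conditional autoregressive
    (ICAR) random effects fitted by a Metropolis-within-Gibbs sampler.
    Includes posterior relative risks, exceedance probabilities, per-area
    trend classification, DIC model comparison, and a synthetic surveillance
    data generator with stored ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
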