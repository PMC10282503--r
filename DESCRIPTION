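Package: cjscommunity
Title: Multispecies Hierarchical Two-Age-Class Cormack-Jolly-Seber Survival
    Models with Climate Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating age-dependent apparent survival and
    recapture probabilities in a community of species from banding
    (capture-mark-recapture) data. Raw banding records are collapsed to
    annual breeding-season capture histories and summarized as
    age-structured m-arrays; a Bayesian hierarchical two-age-class
    Cormack-Jolly-Seber model with community-level hyper-parameters,
    species traits (migratory behavior, body size), and logit-linear
    climate and effort regressions is fitted by adaptive MCMC over the
    marginalized multinomial m-array likelihood. Posterior effect
    indices (probability of direction, highest-density intervals, region
    of practical equivalence coverage), U-CARE-style goodness-of-fit
    tests, covariate construction from daily weather and monthly ENSO
    series, and a full synthetic-study generator for validation are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
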