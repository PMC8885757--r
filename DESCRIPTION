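Package: srwassess
Title: Bayesian State-Space Assessment of Southern Right Whale Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing the recovery of the southwestern Atlantic
    southern right whale (Eubalaena australis) from centuries of commercial
    whaling. Implements reconstruction of an effective annual removals series
    from low/high catch bounds with struck-and-lost corrections, a
    residence-time-corrected cumulative index of arrivals from repeated aerial
    counts (negative-binomial seasonal model plus deconvolution), and an
    age- and sex-aggregated theta-logistic state-space production model fitted
    by sampling-importance-resampling with a backwards (recent-abundance)
    parameterisation. Includes sensitivity scenarios, Bayes-factor model
    averaging, posterior predictive checks, and a synthetic-data generator
    that emulates the catch history, aerial survey counts and absolute
    abundance estimate used in such assessments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mvtnorm,
    withr
Config/testthat/edition: 3
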