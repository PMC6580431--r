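Package: stopmix
Title: Stopover Duration, Timing and Population Size from Mark-Resight
    Data with Finite-Mixture Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Jolly-Seber superpopulation models for estimating stopover
    timing, duration and population size of migratory birds staging at a
    site, from daily resightings of individually marked animals combined
    with scan samples of marked and unmarked birds.  Provides a
    maximum-likelihood (POPAN-style) fitting engine with AICc model
    selection, a Bayesian state-space formulation with parameter-expanded
    data augmentation and two-class finite mixtures in daily staying and
    encounter probabilities, a binomial mark-ratio model that scales the
    marked superpopulation to total population size, a simulator for
    mark-resight and scan data under mixture scenarios, and a simulation
    harness for quantifying the bias induced by unmodelled heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
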