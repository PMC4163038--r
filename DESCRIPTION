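Package: mratio
Title: Metacognitive Efficiency (meta-d'/d') from Confidence-Rated 2AFC Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of meta-d', the signal detection
    theoretic measure of type-2 (confidence) sensitivity, from two-alternative
    forced-choice trials with continuous confidence ratings. Provides type-1
    d'/criterion estimation, within-subject quantile binning of confidence,
    the meta-d'/d' efficiency ratio (M-ratio), the domain-general index
    |log Mp - log Mm|, subject-level percentile bootstrap confidence
    intervals, group comparisons with a permutation group-by-domain
    interaction test, and generative simulators of staircased dot
    discrimination and word recognition tasks with controllable ground-truth
    metacognitive efficiency for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
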