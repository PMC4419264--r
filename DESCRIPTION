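Package: eegfsel
Title: Filter and Wrapper Feature Selection for EEG Band-Power
    Classification
Version: 0.1.0
Authors@R:
    person("BCI", "Tools", email = "bci-tools@example.org", role = c("aut", "cre"))
Description: Three-stage feature selection for multiclass motor-imagery
    brain-computer interfaces operating on Welch band-power (PSD) feature
    vectors. Stage one computes per-feature discriminant character either
    from normalized within-class variances (entropy and product criteria)
    or from the similarity of per-class trapezoidal fuzzy sets extracted
    from a neurofuzzy rule classifier. Stage two scores, orders, and
    preselects candidate features by a cumulative-score threshold. Stage
    three picks the final subset by prefix order selection or by greedy
    GMDH forward selection under a regularity criterion (mean held-out
    accuracy over all learn/prune/test session permutations). The package
    ships the supporting fuzzy-rule classifier (one-pass learning, rule
    pruning, six-model voting), the surface-Laplacian plus sliding-window
    Welch PSD preprocessing chain, a synthetic session generator with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
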