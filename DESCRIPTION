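Package: streamdyn
Title: Decoding and Dynamical-System Modelling of Rapid Visual Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how successive visual stimuli are multiplexed
    in sensor-level brain activity. Provides a discrete-time simulator for
    hierarchical networks of observable and hidden units, a complexity-ordered
    grid search over connection-sign architectures, a synthetic generator for
    rapid serial visual presentation EEG epochs, per-time-sample linear
    decoding of circular stimulus features with grouped cross-validation and
    Haufe pattern transforms, temporal generalization analyses, and
    second-level group statistics including a cluster-based sign-flip
    permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    MASS,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
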