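Package: categru
Title: Category Learning in a Gated Recurrent Network Trained by
    Actor-Critic Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a sequential paired-association task in which an
    agent must chain two stimulus-stimulus associations per trial, and
    trains a sparsely connected continuous-time gated recurrent policy
    network together with a gated recurrent value network by
    policy-gradient actor-critic reinforcement learning.  Provides the
    neuron-level analysis suite used to quantify emergent coding in the
    recurrent layer: per-condition firing-rate tables, the category index
    with its permutation (bootstrap) significance test, the stimulus
    index, neuron taxonomies (silent, stimulus-coding, category-coding),
    direct/indirect input-connectivity splits, learning time courses of
    the indexes, weight-distribution and activity-similarity analyses,
    and action-coding classification.  A synthetic firing-rate generator
    with controllable within- and between-category structure supports
    testing the analysis stages in isolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
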