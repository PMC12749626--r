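Package: miniscifunnel
Title: Machine Learning Funnel for Minisci C-H Alkylation Hit Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reaction-informed hit-to-lead design around Minisci-type
    C-H alkylation of N-heteroarenes. Reads and writes high-throughput
    experimentation reaction tables in a SURF-compatible tab-separated dialect,
    featurizes reactant pairs as molecular graphs with one-hot atom features,
    optional seeded 3D conformer ensembles and Fourier-encoded interatomic
    distances, and trains a graph transformer neural network (twin
    message-passing towers with attention-based multiset pooling and a
    reaction-condition embedding) to predict reaction yield and binary outcome.
    Provides four cross-validation regimes for out-of-distribution evaluation
    (random, unseen arenes, unseen acids, both unseen), virtual library
    enumeration of alkylation products from scaffold and carboxylic-acid lists,
    and a multi-parameter prioritization funnel combining predicted potency,
    synthesizability and ADME annotations. A synthetic data generator with a
    planted, recoverable yield surface makes the whole pipeline testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
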