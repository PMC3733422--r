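Package: corrtrait
Title: Correlated Evolution of Binary Traits on Bootstrap Tree Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood Mk-model analysis of binary characters on
    rooted phylogenies and bootstrap tree ensembles: closed-form and
    matrix-exponential transition probabilities, Felsenstein pruning
    likelihoods (2-state and 4-state), single-rate versus asymmetric-rate
    likelihood-ratio tests, marginal ancestral-state reconstruction by node
    fixing with proportional-likelihood-ratio and two-log-unit significance
    rules aggregated across tree ensembles, Pagel's test of correlated
    evolution between a habitat character and morphological characters with
    median log-likelihood aggregation and a four-degree-of-freedom chi-square
    test, a modified BIC comparison of partitioning schemes, and a seeded
    synthetic-data generator (Yule trees, NNI-perturbed ensembles, forward
    CTMC trait simulation including an event-driven correlated-pair
    simulator).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
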