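Package: morphoclade
Title: Bayesian and Parsimony Phylogenetics for Discrete Morphological
    Characters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for phylogenetic analysis of discrete morphological
    character matrices: NEXUS input/output with polymorphism, ordering and
    exclusion metadata; quantitative-character binarization at the
    across-species median and majority coding of polymorphisms; an Mk/Mkv
    likelihood engine with discrete-gamma rate variation, ordered-state
    chains and variable-characters-only ascertainment correction; Bayesian
    MCMC over topology, branch lengths and gamma shape with split-frequency
    convergence diagnostics (ASDSF); majority-rule consensus with posterior
    probabilities, harmonic-mean marginal likelihoods and Bayes factors;
    posterior monophyly hypothesis testing with branch-length-corrected
    clade credibility; maximum parsimony with Fitch and Sankoff scoring,
    heuristic and exhaustive search, nonparametric bootstrap and Bremer
    decay indices; and a seeded synthetic-data generator for trees,
    Mk(+gamma)-evolved matrices and Brownian quantitative traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
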