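Package: brainstates
Title: Latent Brain-State Dynamics of Naturalistic fMRI via Gaussian Hidden
    Markov Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers latent whole-brain states from network-level BOLD time
    series recorded during naturalistic listening. Fits multivariate
    Gaussian-emission hidden Markov models with restarts, selects the number
    of states by a dual criterion (Calinski-Harabasz clustering quality plus
    narrative decoding accuracy under leave-one-subject-out
    cross-validation), summarizes state dynamics (fractional occupancy,
    dwell time, transition-hub asymmetry) against circular-shift surrogate
    nulls, contrasts per-state network topology (weighted global efficiency
    and Louvain modularity), reconstructs metastates from finer models by
    clustering the transition matrix, matches states across conditions,
    tests stimulus-feature modulation of state expression with
    HRF-convolved regressors and permutation, and predicts comprehension
    from inter-subject alignment of state expression. Ships a synthetic
    cohort generator that emulates the statistical structure of such
    studies so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'behavior.R'
    'brainstates-package.R'
    'dynamics.R'
    'graph.R'
    'hmm.R'
    'io.R'
    'metastate.R'
    'pipeline.R'
    'selection.R'
    'stimulus.R'
    'studies.R'
    'synthetic.R'
    'utils.R'
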