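Package: msmpath
Title: Markov State Models and Transition Path Analysis for Adaptively Sampled Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for quantifying binding/unbinding kinetics of
    biomolecular complexes from tree-connected, adaptively reseeded replica
    simulation ensembles. Provides distance-based featurization of
    protein-RNA complexes (differential contact maps, sigmoidal distance
    transforms, principal-component reduction), multi-resolution tree
    clustering, Markov state model estimation with sliding-window transition
    counts that respect reseeding tree connectivity and geometrically
    informed pseudocounts, transition-path-theory committors, reactive
    fluxes and mass-action rate constants (k_on, k_off, K_D) with
    count-subsampling confidence intervals, Kemeny-constant network
    diagnostics, progress-index (SAPPHIRE) trajectory annotation, a
    progress-index-guided adaptive sampling (PIGS) controller operating on
    pluggable toy propagators, dihedral-ensemble comparison tools
    (periodicity-safe PCA, Kullback-Leibler divergence, mutual information,
    sugar-pucker pseudorotation), and synthetic dynamics generators with
    analytic kinetic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    yaml,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
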