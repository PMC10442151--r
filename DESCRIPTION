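Package: isafit
Title: Geometric Interpenetration Scoring and Conformational Analysis of
    Ubiquitylated Linker Histones
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to screen conformational ensembles of ubiquitylated
    linker histones (HUb) against nucleosome and chromatosome receptor
    structures. Implements the interpenetration and scoring algorithm
    (ISA): a min-merged cumulative 3D occupancy grid built from receptor
    atom positions, against which superposed ligand poses are scored by
    summing normalized per-atom bin values. Also provides the supporting
    machinery: collective-variable extraction (surface-exposed C-alpha
    distance sets and residue-wise minimal distances), Kabsch rigid-body
    superposition with sequence-alignment fallback, iterative
    density-based (HDBSCAN) cluster refinement with structure-homogeneity
    gating, restart selection from sparsely populated projection bins for
    adaptive sampling, and deterministic synthetic-data generators for
    testing every component without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    withr,
    e1071,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    quadprog
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
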