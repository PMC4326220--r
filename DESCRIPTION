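Package: mimoprune
Title: Conformational B-Cell Epitope Prediction by Antigen Surface
    Pruning and Mimotope Patch-Graph Alignment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage prediction of conformational B-cell epitopes from an
    antigen 3D structure and a phage-display mimotope set. Stage one computes
    six per-residue epitope propensity features on the solvent-accessible
    antigen surface and prunes residues voted "nonepitope" by an ensemble of
    random forests trained on class-balanced subsamples. Stage two divides the
    pruned surface into overlapping patches whose residue adjacency graphs use
    an adaptive distance threshold regulated by a compactness factor, aligns
    each mimotope to simple paths in every patch graph by complete dynamic
    programming with branch-and-bound pruning, converts raw alignment scores
    to Gumbel extreme-value P-values calibrated on random peptides, and
    reports the residues of the highest-scoring patch as the predicted
    epitope. Includes epitope annotation from antigen-antibody complexes by
    accessible-surface-area loss, the standard residue-level evaluation
    metrics over the antigen-surface universe, and generators for synthetic
    antigens with planted epitopes and matching noisy mimotopes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    randomForest,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
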