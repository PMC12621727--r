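Package: ensdesign
Title: Ensemble-Conditioned Potts Models for Fixed-Backbone Protein Sequence Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-structure Potts sequence models over amino acids, averages
    their sitewise fields and pairwise couplings across a conformational ensemble
    (a product-of-experts over per-conformer sequence distributions), and samples
    sequences from the averaged model with discrete Markov chain Monte Carlo
    (Discrete Langevin Monte Carlo and Gibbs) under an optional local composition
    perplexity restraint. Includes backbone PDB input, Kabsch superposition and
    RMSD, Gaussian-noise ensemble generation, k-nearest-neighbour graph
    featurization, a toy trainable graph network with a Potts readout and
    pseudolikelihood training, sequence-recovery and PSSM-similarity evaluation
    statistics, deterministic synthetic fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    seqinr,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
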