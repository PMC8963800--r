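Package: plantppi
Title: Plant Protein-Protein Interaction Prediction from PSSM Texture
    Features with a Rotation Forest
Version: 0.1.0
Authors@R:
    person("plantppi", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-based prediction of plant protein-protein
    interactions. Protein sequences are encoded as position-specific
    scoring matrices (PSSMs), summarized by the LOOP local texture
    descriptor (eight Kirsch directional masks, rank-weighted binary
    codes) into 256-bin histograms, concatenated per protein pair, and
    classified with a from-scratch rotation forest ensemble (per-subset
    PCA rotations over bootstrapped subsamples, unpruned CART base
    trees). Includes a PSI-BLAST ASCII PSSM parser, a deterministic
    pseudo-PSSM generator so the whole pipeline runs without PSI-BLAST,
    compartment-aware negative-pair sampling, a synthetic benchmark
    generator, k-fold cross-validation with Acc/Sen/Prec/Spec/MCC/AUC
    reporting, an (L, K) grid search, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
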