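---
title: "PSSM texture descriptors and rotation forests for plant PPI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSSM texture descriptors and rotation forests for plant PPI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantppi)
```

## The problem and the model

Experimentally validated plant protein–protein interactions (PPIs) are
scarce relative to the size of plant proteomes, and the assays that produce
them (yeast two-hybrid, AP-MS, protein microarrays) are expensive and
noisy. Sequence-based prediction fills the gap: given only two amino-acid
sequences, estimate whether the proteins interact.

This package implements a three-stage pipeline:

1. **Evolutionary profile.** Each protein is represented by its
   position-specific scoring matrix (PSSM), a 20 × M matrix of
   substitution log-odds scores (M = sequence length; rows in the fixed
   PSI-BLAST order `ARNDCQEGHILKMFPSTWYV`). PSSMs are normally produced by
   PSI-BLAST against a reference database (three iterations, e-value
   0.001 are the conventional settings, exposed as defaults in the
   documentation of `parse_psiblast_pssm()`); the package parses that
   ASCII format but never runs PSI-BLAST itself. For offline work and
   testing, `pseudo_pssm()` builds a deterministic stand-in: column j is
   the BLOSUM62 row of residue j plus seeded Gaussian noise.

2. **Local texture descriptor.** The PSSM is treated as a 20 × M image
   and summarized by the LOOP (local optimal-oriented pattern) code. For
   every interior cell, the eight ring neighbours are thresholded against
   the center (`s(i_n - i_c)` with `s(x) = 1` iff `x >= 0`), and each
   neighbour's bit weight `2^w_n` is set by the rank of the magnitude of
   its Kirsch directional edge response among the eight responses
   (largest magnitude gets exponent 7). The resulting 8-bit codes
   (0–255) are binned into a 256-component histogram per protein — the
   LOOP merges the thresholding of LBP with the directional ranking of
   LDP, removing LBP's arbitrary start-of-ring choice.

3. **Classifier.** A protein pair is the concatenation of its two
   descriptors (512 features). A rotation forest is fitted: each of L
   trees gets its own random partition of the features into K subsets;
   per subset, PCA is fitted on a bootstrapped 75 % subsample and the
   per-subset axes are assembled into a sparse block-diagonal n × n
   rotation, rearranged back to original feature order; an unpruned CART
   tree is trained on the rotated data. Test confidences are the average
   of the L trees' leaf class frequencies; the predicted class is the
   argmax. The operating point L = 3, K = 10 is the package default.

Evaluation follows the standard protocol: five-fold cross-validation at
the pair level with accuracy, sensitivity, precision, specificity, MCC
and ROC-AUC, reported per fold and as mean ± sample standard deviation,
plus an (L, K) grid search.

## Fixed conventions and tunable parameters

* **Neighbour ring / masks.** n = 0..7 enumerates the 3 × 3 ring
  clockwise from the top-left offset (−1,−1); Kirsch mask n carries +5 on
  neighbour n and its two ring-adjacent neighbours, −3 on the other five,
  0 at the center. Every mask sums to zero (so responses ignore local
  DC level) and mask n is the 45° rotation of mask n−1. The literature
  fixes the mask shapes but not the index order; histograms produced
  under any fixed order are permutations of one another, so the choice is
  documented rather than consequential.
* **Ties.** Equal response magnitudes: the smaller direction index gets
  the larger exponent. A constant patch therefore always maps to code
  255, and codes are deterministic.
* **Borders.** Only cells with a complete 3 × 3 neighbourhood are coded
  (18 × (M−2) cells); padding would invent data, and the ≥ 50-residue
  filter guarantees M ≥ 3 in practice.
* **Histogram normalization.** Counts are normalized to frequencies so
  proteins of different lengths are comparable; raw counts would encode
  M, which is not claimed as a feature. (Whether the original
  experiments used counts or frequencies is not stated; frequencies are
  the defensible choice and the classifier is insensitive to a global
  per-protein scale.)
* **PSSM values are used raw.** No sigmoid or min–max rescaling: the
  LOOP code is invariant to shifts and positive scalings of the input,
  so rescaling could only discard information (and the thresholding step
  makes it unnecessary).
* **Rank on magnitudes.** Exponents rank |m_n|, not signed responses —
  the descriptor's published wording — so an edge and its reversal get
  the same weight ordering.
* **Rotation forest.** `L` (trees, default 3) and `K` (feature subsets,
  default 10) trade accuracy against cost and are the grid-search
  dimensions. The bootstrap is 75 % of the objects, drawn *with*
  replacement (classical rotation-forest formulation; the source
  protocol fixes the size but not the replacement convention).
  Rank-deficient PCA blocks (bootstrap smaller than the subset width)
  are completed to a full orthonormal basis by QR so every per-block map
  stays invertible; zero-padding would silently delete features. Each
  block stores the bootstrap-sample mean and subtracts it before
  projection at both fit and predict time. Per-member and per-block
  seeds derive from the master seed by an integer hash (`derive_seed`),
  so members differ but runs reproduce bit-for-bit. The base learner is
  an unpruned CART tree with Gini impurity, written in-package (no tree
  library is assumed by the implementation). The class-conditional
  subset randomization of some rotation-forest variants is deliberately
  not implemented: the protocol followed here bootstraps objects only.
* **Pair features.** Concatenation `[a ‖ b]` in the given order — the
  conventional choice in sequence-based PPI work when the combination
  rule is otherwise unspecified. An optional both-orders augmentation
  (`build_interaction_dataset(..., both_orders = TRUE)`) symmetrizes
  training but is off by default.
* **Folds.** Plain random pair-level folds by default ("randomly
  separates" is the stated protocol); note this allows the same protein
  to occur in train and test pairs — a known optimistic bias of the
  standard protocol that is reproduced as-is, not corrected.
* **Undefined metrics** (zero denominators) are reported as `NA` with a
  warning, never coerced to 0, so fold summaries are not silently
  distorted. Fold standard deviations use the sample convention
  (divisor k − 1). AUC uses grouped tied thresholds, so the trapezoidal
  area equals the Mann–Whitney statistic with ties counted ½; it is
  computed per fold and averaged, matching the per-fold presentation of
  the evaluation protocol.

## The synthetic benchmark: what it emulates, and what a green test shows

Real gold-standard datasets (tens of thousands of pairs, PSI-BLAST
against SwissProt) are out of scope at desk scale, so the package ships a
generator whose output exercises every stage of the pipeline:

* Sequences are uniform over the 20 canonical residues, lengths 50–70 by
  default (the short end of real proteins, chosen to keep desk-scale
  runtimes; all generated proteins pass the ≥ 50-residue filter).
* Profiles are `pseudo_pssm()` draws: BLOSUM62 columns plus unit-sd
  noise. Note the background is itself textured — adjacent columns
  differ by the residues' BLOSUM rows — which is what a texture motif
  must compete against.
* **Class signal.** One smooth 20 × 21 "interface motif" patch is drawn
  per dataset (white noise passed once through a 3 × 3 box filter,
  scaled to unit sd times `signal_strength`); both partners of every
  positive pair carry it, inserted at protein-specific random column
  offsets (harmless to the descriptor, whose histogram discards
  position). Every other protein carries its *own* independent random
  patch of identical amplitude, so the two classes differ only in which
  texture they carry, never in whether they carry one.
* **Vertex-disjoint pairs.** Every protein occurs in exactly one pair
  (`n_prot >= 2 * (n_pos + n_neg)` is enforced). Two failure modes of a
  shared pool motivated this: a protein in pairs of both classes makes
  the labels contradict the per-protein features (a profile cannot both
  carry and not carry the motif), and with reuse but class-disjoint
  pools a tree can recognise individual proteins across folds, producing
  AUC ≈ 0.9 at `signal_strength = 0` out of pure identity memorisation.
  Disjoint pairs remove both artifacts: the null world measures exactly
  chance (AUC ≈ 0.5), and the strong-signal world measures genuine
  generalization to unseen proteins.
* **Amplitude.** The default `signal_strength = 80` (in log-odds units;
  the "strong" benchmark setting, frozen after a pilot) is what it takes
  for motif-induced codes to dominate the BLOSUM background contrast
  reliably; at 0 the classes are identically distributed by
  construction.

A green end-to-end test (five-fold accuracy ≥ 90 % at strong signal,
AUC in [0.45, 0.55] at zero signal) therefore establishes that the
descriptor transmits a planted local-texture difference through to the
classifier and that the pipeline does not manufacture signal from noise.
It does **not** establish anything about accuracy on real interactomes:
real positives are not defined by a single shared motif, real profile
backgrounds are not i.i.d. BLOSUM-plus-noise, real datasets reuse
proteins across pairs, and redundancy filtering (≤ 40 % identity) is not
modelled.

The second benchmark, `gen_rotated_gaussian()`, is the classical setting
where rotation ensembles beat single axis-aligned trees: two Gaussian
classes sharing an anisotropic covariance with randomly rotated principal
axes and an oblique mean shift. The acceptance property is the paired
mean difference in CV accuracy (rotation forest minus single unpruned
tree) over 10 seeds being non-negative — a weak, directional claim by
design; individual seeds may go either way.

## Numerical and degenerate-input choices

* `parse_psiblast_pssm` reads only the first 20 score columns (log-odds);
  whether the original experiments used the log-odds or the
  weighted-percentage block is unstated, and log-odds is the standard
  choice. Truncated rows and non-numeric cells fail with the line
  number; a header-only file fails as degenerate.
* Non-canonical residues (B, Z, J, U, O, `*`, anything else) are mapped
  to `X` with a warning; `pseudo_pssm` gives `X` the average of the 20
  profile rows. PSI-BLAST files are taken as printed.
* A constant PSSM yields the one-point histogram at code 255, not an
  error; an M < 3 PSSM raises "sequence too short for texture window".
* Bootstrap draws with fewer than two distinct rows are reseeded a
  bounded number of times (10) before failing — relevant only for
  pathological constant inputs.
* Grid-search ties resolve toward smaller L, then smaller K (the cheaper
  model), making the search deterministic.
* Model archives are fully boxed JSON at full precision
  (`rotation_forest/1` schema); a reloaded model reproduces the
  original's predictions exactly.

## Known limitations

* Pure-R tree growth is the computational bottleneck; the intended
  operating range (hundreds to a few thousand pairs, 512 features) runs
  in seconds to minutes, but genome-scale training would want a compiled
  base learner.
* The pair representation is order-sensitive; callers who need symmetry
  must opt into the both-orders augmentation.
* Pair-level cross-validation shares proteins between train and test
  pairs on real data (not in the vertex-disjoint synthetic benchmark);
  reported numbers on real interactomes are optimistic in the usual,
  well-documented way.
* The PSI-BLAST wrapper is documentation-only: the package parses
  profiles, it does not produce them.
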