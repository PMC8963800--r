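# plantppi

Sequence-based prediction of plant protein–protein interactions (PPIs)
from evolutionary profiles, for computational biologists who have protein
sequences (and, ideally, PSI-BLAST profiles) but no interaction assay.

Experimental PPI detection in plants is expensive and incomplete, so
in-silico screening from sequence alone is a standard first pass. The
pipeline implemented here:

1. **PSSM** — each protein is a 20 × M position-specific scoring matrix
   `P = {P_ij}` (rows = amino acids in PSI-BLAST order
   `ARNDCQEGHILKMFPSTWYV`, columns = positions, entries = substitution
   log-odds). Parsed from `psiblast -out_ascii_pssm` files, or generated
   offline as a deterministic BLOSUM62-plus-noise stand-in
   (`pseudo_pssm()`).
2. **LOOP descriptor** — the PSSM is read as a texture image. Every
   interior cell gets an 8-bit local optimal-oriented pattern code

   LOOP(x_c, y_c) = Σ_{n=0..7} s(i_n − i_c) · 2^{w_n},  s(x) = 1 iff x ≥ 0,

   where `i_0..i_7` are the ring neighbours of center `i_c` and the
   exponent `w_n` is the rank of |m_n|, the magnitude of the n-th Kirsch
   directional mask response, among all eight responses. The protein is
   the 256-bin frequency histogram of its codes.
3. **Rotation forest** — a pair is the 512-vector `[a ‖ b]` of the two
   histograms. Each of L = 3 unpruned CART trees trains on data rotated
   by a sparse block-diagonal matrix of per-feature-subset PCA axes
   (K = 10 subsets, PCA on a 75 % bootstrap subsample per subset,
   rearranged to original feature order). Class confidences are averaged
   over trees: μ_k(x) = (1/L) Σ_i d_{i,k}(x R_i^a).
4. **Evaluation** — five-fold cross-validation with accuracy,
   sensitivity, precision, specificity, MCC =
   (TP·TN − FP·FN)/√((TP+FP)(TN+FP)(TP+FN)(TN+FN)), and Mann–Whitney
   ROC-AUC, reported per fold and as mean ± sd, plus an (L, K) grid
   search.

A bundled synthetic-benchmark generator (`gen_synthetic_ppi()`) plants a
shared "interface motif" texture in the profiles of interacting partners,
so the whole pipeline is testable with no downloads; see the methods
vignette (`vignettes/methods.Rmd`) for what it does and does not emulate.

## Worked example

```r
library(plantppi)

# a bundled PSI-BLAST ASCII profile for a 60-residue protein
fx <- system.file("extdata", "example60.pssm", package = "plantppi")
p <- parse_psiblast_pssm(fx)
p
#> PSSM 'example60' (psiblast): 20 x 60
h <- loop_histogram(p)
h
#> LOOP descriptor 'example60': 256 bins, 207 occupied

# synthetic benchmark: 120 vertex-disjoint pairs, default strong signal
ds  <- gen_synthetic_ppi(n_prot = 240, n_pos = 60, n_neg = 60, seed = 7)
idt <- synthetic_interaction_dataset(ds)
idt
#> Interaction dataset: 120 pairs (60 positive), 240 proteins, 512 features
cross_validate(idt, rof_config(L = 3, K = 10, seed = 7), k = 5, seed = 7)
#> 5-fold cross-validation (L = 3, K = 10)
#>   accuracy     88.33 +/- 4.56 %
#>   sensitivity  96.79 +/- 4.39 %
#>   precision    83.26 +/- 6.95 %
#>   specificity  80.01 +/- 9.08 %
#>   mcc          78.07 +/- 8.35 %
#>   auc          0.9448 +/- 0.0434
```

The classifier recovers the planted interaction signal well above chance
(88 % accuracy, AUC 0.94 on 120 pairs; the acceptance-scale benchmark
with 400 pairs reaches ≥ 90 %); with `signal_strength = 0` the same
pipeline stays at chance (AUC ≈ 0.5), confirming it does not manufacture
signal.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("exec/plantppi", package = "plantppi"))')
Rscript $CLI simulate --out-dir bench --seed 11          # synthetic dataset
Rscript $CLI features --fasta bench/proteins.fasta \
                      --pssm-dir bench/pssm --out bench/features.tsv
Rscript $CLI eval     --pairs bench/pairs.tsv --descriptors bench/features.tsv \
                      --out-prefix bench/cv --seed 11    # CV report (TSV+JSON)
```

Also available: `train`, `predict` (JSON model archive), `grid` (L, K
search), `--config FILE` for flat key=value configs. Logs go to stderr,
results to files; exit codes: 0 ok, 1 usage, 2 data error.

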