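# mhcqsar

QSAR modelling of peptide binding to MHC class I and class II molecules
in R, for immunoinformaticians who want local, inspectable prediction
models rather than web-server black boxes.

## What it does

T-cell epitope discovery starts with predicting how strongly peptides
bind MHC molecules. `mhcqsar` implements a chemometric route to that
prediction:

1. **z-scale encoding.** Each amino acid is represented by its scores
   (z1, z2, z3) on the first three principal components of a large
   panel of physicochemical property scales — z1 tracks
   polarity/hydrophobicity, z2 molecular size, z3 electronic character.
   A 9-mer becomes a 27-vector, a 15-mer a 45-vector:
   {z1(aa1), z2(aa1), z3(aa1), ..., z3(aaL)}. The package ships the
   canonical three-component table (`canonical_zscales()`) and can
   derive fresh z-scales from any 20 x P property table by
   correlation-matrix PCA (`compute_zscales()`).

2. **Per-allele PLS regression with VIP.** ln(ic50) is regressed on the
   descriptors by NIPALS partial least squares (`fit_pls()`), with the
   latent dimensionality chosen by cross-validated PRESS
   (`select_factors()`). The variable importance in projection
   (`compute_vip()`) aggregates squared PLS weights across dimensions,
   weighted by each dimension's explained response sum of squares:

   VIP_k = sqrt( K * Σ_a [ w_ak² (SSY_{a-1} − SSY_a) ] / (SSY_0 − SSY_A) )

   Squared VIPs sum to K, so descriptors with VIP > 1 are the ones that
   matter; mapped back onto the binding groove (P1..P9 for class I,
   N-3..C+3 flanking for class II 15-mers) the VIP grid is a statistical
   picture of the binding pocket (`render_vip_heatmap()`).

3. **Perceptron ensembles.** A nonlinear alternative: single
   hidden-layer perceptrons with logistic activation, hidden width equal
   to the binding-domain length (9 or 15), linear output, and an L2
   overfitting penalty tuned so training r² ≈ 0.9
   (`tune_penalty()`). Two cross-validation schemes: Method 1
   (`train_method1()`) runs multiple random-holdback tours and keeps the
   tour that generalizes best; Method 2 (`train_method2()`) trains nine
   members on random 2/3 subsets — each peptide serves in about six
   training cohorts — and `predict_ensemble()` reports the member mean,
   its SEM, and a CV% per peptide.

4. **Evaluation and data handling.** Strong/weak/non-binder categories
   (SB ≤ 50 nM < WB ≤ 500 nM < NB), Mann–Whitney AROC with half-credit
   ties (`auroc()`), Pearson r² (`evaluate()`); TSV binding tables,
   FASTA reading, random proteome k-mer test sets (`sample_kmers()`);
   and a synthetic-data generator (`generate_dataset()`) that emulates
   the documented pathologies of public IEDB-style benchmark data —
   overlapping peptide subsets with ln-mean differences of 2.2, and
   censoring spikes at the 1 / 20,000 / 78,125 nM assay limits — so the
   whole pipeline is testable without any download.

## Worked example

```r
library(mhcqsar)

# synthetic class II dataset: 399 15-mers, a planted 6-descriptor
# effect, subset structure and assay-limit censoring
beta <- generate_linear_truth(length = 15, sparsity = 6,
                              effect_scale = 0.4, seed = 42)
cfg  <- synthetic_config(true_effect = beta, seed = 42)
ds   <- generate_dataset(cfg)

enc <- encode_dataset(ds)                      # 399 x 45 matrix + ln(ic50)
A   <- select_factors(enc$X, enc$y, max_factors = 5)
m   <- fit_pls(enc$X, enc$y, A, allele = ds$allele[1])
m
#> PLS model [SYN-DRB1*0101]: 1 factors, K = 45 descriptors, n = 399
#> response SS explained: 0.245

vip <- compute_vip(m)
sum(vip$vip_flat^2) / 45                       # VIP normalization
#> [1] 1
which(vip$values > 1, arr.ind = TRUE)          # relevant groove cells
#>   position component  vip
#> 1      N-3       PC1 1.85
#> 2       P1       PC1 2.61
#> 3       P6       PC1 3.21
#> 4      C+1       PC1 4.44
#> 5       P9       PC3 1.03

evaluate(predict(m, enc$X), ds$ic50_nM, allele = ds$allele[1])
#> evaluation [SYN-DRB1*0101]: n = 399, r2 = 0.245,
#>   AROC(SB) = 0.732, AROC(WB) = 0.727
```

The planted effect sat on positions N-3, P1, P3, P6, P9 and C+1; five
of the six surface with VIP > 1 (an r² of 0.25 is typical here — the
subset offsets and censoring are deliberately not predictable from
sequence, mimicking real training sets). `render_vip_heatmap(vip,
"vip.png")` draws the groove importance map with its numeric sidecar
TSV.

A command-line front end covering simulate / train / predict /
evaluate / sample-kmers / heatmap lives at
`system.file("cli", "mhcqsar", package = "mhcqsar")`.

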