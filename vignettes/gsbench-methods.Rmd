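---
title: "Benchmarking genomic prediction models and reducing marker panels with gsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking genomic prediction models and reducing marker panels with gsbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsbench)
```

## What the package does

`gsbench` implements a genotype-to-phenotype prediction workflow of the kind
used in genomic selection studies on crop diversity panels: SNP genotypes are
filtered, thinned and one-hot encoded; four model families (XGBoost, random
forest, a 1D convolutional network and a dense network) are benchmarked under
k-fold cross-validation with a held-out evaluation set; the fitted XGBoost
model is interpreted through its gain-based feature importance; top-ranked
SNPs are chained into *Regions of Importance* (ROIs); a single-marker
association scan cross-checks those regions against significantly associated
loci; and finally the marker panel is reduced to the targeted regions and the
benchmark is re-run on the reduced input.

Because real diversity-panel data (hundreds of accessions, millions of
markers) is external and large, the package ships a synthetic
genotype/phenotype generator whose defaults emulate the statistical structure
the workflow assumes. Every stage is therefore testable at desk scale.

## The synthetic generator

### Genotypes

`simulate_genome_map()` places SNPs uniformly on each chromosome;
`simulate_genotypes()` draws, per line, two haplotypes under near
Hardy-Weinberg equilibrium. Local linkage disequilibrium is created with a
latent-signal model: each chromosome is tiled into blocks of
`ld_block_span_bp` (default 150 kbp); within a block each haplotype carries
one latent standard-normal signal, and each SNP's allele indicator thresholds
a mixture

$$ z_{ij} = \sqrt{\rho}\, u_{i,b(j)} + \sqrt{1-\rho}\,\varepsilon_{ij},
\qquad \text{allele}_{ij} = \mathbb{1}\{z_{ij} < \Phi^{-1}(p_j)\} $$

with $\rho$ = `within_block_correlation` (default 0.8) and $p_j$ the SNP's
target allele frequency, drawn uniformly from `maf_range` (default
[0.05, 0.5], matching the 0.05 MAF floor the preprocessing filter enforces).
Thresholding a Gaussian copula rather than copying-with-flip-noise was a
deliberate choice: it preserves each SNP's marginal allele frequency exactly
(so realized MAF converges to its target as the panel grows — a property the
test suite checks at n = 200 vs n = 2000) while still giving tunable local
r² and exact independence across blocks. The realized dosage r² between
adjacent in-block SNPs is necessarily lower than $\rho$ (double dichotomised
correlation); at $\rho = 0.9$ it averages roughly 0.25–0.35, which is within
the range reported for dense panels in selfing crops. No coalescent realism,
recombination map or mutation model is attempted; blocks have hard
boundaries, which real LD does not.

Missing calls are dropped uniformly at random (`missing_rate`, default
0.005): the preprocessing filters act on missingness *rates*, so the
missingness *mechanism* is irrelevant to what they test. An optional
two-subpopulation mode shifts allele frequencies apart by
`subpop_divergence`, giving the population structure the association scan's
principal-component covariates are meant to absorb.

### Traits

Categorical traits are near-Mendelian: a penetrance matrix (rows = causal
genotype REF_HOM/HET/ALT_HOM, columns = classes) gives each line's class
distribution; `dominant_penetrance(1)` is the fully deterministic dominant
case. With two causal loci the per-locus distributions are averaged — a
simple mixing rule, not an epistasis model.

Continuous traits are additive: genetic value $g_i = \sum_j d_{ij}\beta_j$
over causal loci on the 0/1/2 dosage scale, plus Gaussian noise with variance
$\sigma_e^2 = \sigma_g^2 (1-h^2)/h^2$ so the genetic variance fraction
matches the target heritability. The trait is then shifted to
$\bar y = 3\,\mathrm{sd}(y)$ so the mean is strictly positive — the
regression metric divides by the trait mean, and a near-zero mean would make
it explode. Dominance and epistasis are not simulated by default; the
benchmark therefore measures how the model families rank on an (almost)
additive architecture, and nothing here speaks to their relative merits on
strongly non-additive traits.

## Preprocessing

The canonical filter order is `filter_lines()` (drop lines with *over* 1%
missing calls — the boundary is kept), then `filter_snps()` (keep MAF ≥ 0.05
computed over non-missing calls, and missing rate strictly below 10%), then
`thin_sequential()` (keep 1 SNP in 20 in genome order, a 95% density
reduction). The order is fixed for reproducibility; whether thinning precedes
or follows the marginal filters changes which SNPs survive, and no single
order is canonical in practice, so the package picks one and applies it
everywhere.

One-hot encoding emits one indicator column per genotype class *observed* at
each SNP — classes absent from the sample would be constant-zero columns and
are skipped; the feature index makes the encoding lossless anyway
(`decode_feature()` recovers SNP, genotype class and rendered allele pair for
any emitted column). A missing call encodes as all zeros across its SNP's
columns; no imputation is attempted. Holdout splitting takes a uniform 20%
round-half-up sample; stratified sampling is available but off by default,
since plain random exclusion is the textbook protocol this mirrors.

## The model families

All four families consume the same one-hot matrix; the CNN reads it as a
single-channel 1D sequence in genome order. Architecture constants are fixed:

* **XGBoost** — default booster with 100 rounds, or hyperparameters from
  `tune_xgboost()`: sequential model-based search (Latin-hypercube start,
  random-forest surrogate, expected improvement) over learning_rate
  [0.01, 1], min_child_weight [0, 10], max_depth [0, 50], max_delta_step
  [0, 20], subsample/colsample_bytree/colsample_bylevel [0.01, 1], reg_lambda
  [1e-9, 1000], reg_alpha [1e-9, 1], gamma [1e-9, 0.5], n_estimators
  [50, 200] and scale_pos_weight [1e-6, 500], scored by inner 3-fold CV.
  Default budget 25 evaluations — a tractable default; raise it for serious
  tuning.
* **Random forest** — 100 trees, square-root feature subsampling.
* **CNN** — three 1D ReLU convolutions (12/10/8 filters, kernels 14/10/8)
  with 20% dropout between stages 1–2 and 10% between 2–3, a size-2 max pool,
  batch normalisation, then ReLU dense layers 48/32/16 each followed by batch
  normalisation.
* **DNN** — ReLU dense layers 200/100/64/32/16 with 3/2/1% dropout after the
  first three and batch normalisation after the last.

The networks train with Adamax at learning rate 0.003 and a batch size of
1/50th of the training samples. The training budget — at most 200 epochs with
early stopping on a 10% validation slice (patience 20, best weights
restored) — is the package's own choice for bounded CPU runtime. The layers
and optimiser are implemented in-package (R has no installed deep-learning
framework here); backpropagation is verified against numerical gradients in
the test suite, and seeds make runs reproducible.

Cross-validation uses k = 10 (stratified for classification), and the model
kept for holdout prediction is the *best fold's* model used as-is — not
refit on the full training set. Classification is scored as accuracy (%);
regression as RMSE divided by the *full-dataset* trait mean, ×100. Fixing the
denominator per trait before splitting keeps the metric comparable across
models and datasets. Cross-model summaries report each tree family's mean
difference from the unweighted CNN/DNN average (per trait, then averaged) and
a best-model tally per trait × dataset; ties go to the earlier family in
XGB, RF, CNN, DNN order and are logged.

## Regions of Importance and input reduction

`rank_features_by_gain()` ranks one-hot features by the booster's gain (the
total objective improvement attributed to splits on the feature, normalised
over the model) and decodes them to SNPs; each one-hot column is its own
entry, so a SNP can appear with several genotype classes. Gain ties break by
(chrom, pos) for stability. `cluster_rois()` chains top-ranked SNPs per
chromosome by single linkage with a 100 kbp nearest-neighbour gap — chaining,
not an all-pairs clique, because the membership rule is about each SNP's
*nearest* neighbour — and keeps chains of ≥ 3 distinct SNPs. Duplicate
entries of one SNP count once toward the size but their gains sum.

`define_target_regions()` turns ROIs into extraction intervals (flank
default 0). Traits with no ROI fall back to ±250 kbp windows around each
top-ranked SNP; the window half-width is a configurable package decision —
wide enough to cover the local LD neighbourhood of a lone marker, narrow
enough that 20 windows still reduce a genome-scale panel severalfold.
Overlapping intervals merge (via IRanges; coordinates are 1-based closed,
the VCF convention).

## The association scan

`assoc_scan()` is a covariate-adjusted single-marker scan and is an explicit
stand-in for iterative pseudo-QTN methods (FarmCPU): it produces a
threshold-comparable list of significant loci, not FarmCPU's fixed/random
alternation. Population structure is controlled with the first three
principal components of the (mean-imputed, centered) dosage matrix.
Continuous traits use the exact linear-model t-test of the dosage
coefficient, computed for all SNPs at once by residualising phenotype and
dosages on the covariates (verified against per-SNP `lm()` in the tests).
Categorical traits are scanned one-vs-rest on 0/1 class indicators with the
same linear test — the standard case-control coding, chosen over logistic
Wald tests because fully penetrant loci cause complete separation, where the
Wald statistic collapses; the per-SNP minimum p over classes is
Bonferroni-corrected by the class count. Monomorphic SNPs are recorded with
p = 1 and flagged, never dropped silently. The significance threshold is
0.05/m for m tested markers.

## Numerical and degenerate-input choices

* Holdout size: round-half-up of fraction × n; empty train or holdout errors.
* Stratified folds require every class to have ≥ k members; the offending
  class is named in the error.
* Train/holdout leakage is a hard error keyed on line ids.
* `rmse_percent_of_mean()` rejects a zero reference mean.
* A SNP with all calls missing is removed by the SNP filter and counted.
* The CNN rejects inputs shorter than its receptive-field minimum
  (`cnn_min_features()`, 31 features) with the minimum stated.
* Master seed discipline: `run_full_experiment()` derives each stage's seed
  from the master seed by fixed offsets, so stages are independently
  reproducible; tree-based stages are bit-reproducible, network stages are
  reproducible to the engine's own determinism (fixed shuffling, dropout and
  initialisation under seed).

## What the tests do and do not show

The suite runs the generator at desk scale: heritability recovery within
±0.05 (n = 2000, h² ∈ {0.2, 0.5, 0.8}), MAF recovery, LD block structure,
type-I error calibration of the scan in [0.035, 0.065] at nominal 0.05,
≥ 90% power for a 1-SD planted locus at the 0.05/m threshold (n = 500,
m = 500), exhaustive-oracle equivalence of ROI chaining, recovery of a
planted 5-SNP/80-kbp causal cluster as an overlapping ROI in ≥ 80% of seeded
runs (n = 500 × 5,000 SNPs), and region-guided reduction on a monogenic trait
that keeps < 30% of SNPs while XGBoost holdout accuracy stays within 2
points of the full input. The model-benchmarking experiments in the report
machinery use n in the low hundreds and a few hundred SNPs so the full
pipeline (including the neural families) runs in minutes on one CPU.

Passing these tests shows the machinery is correct and calibrated on data
satisfying the generator's assumptions — additive architecture, block LD,
random missingness, near-HWE. It does not show that any family will win on a
real crop panel, where LD decays smoothly, traits have non-additive
components, and missingness tracks genotyping chemistry. The benchmark's
*procedure* transfers; its desk-scale *rankings* do not.

## Known limitations

* The in-package neural engine is CPU-only, dense-matrix, and modest in
  scale; it is not a general DL framework.
* On small panels the prescribed batch rule (n/50) makes the CNN's
  batch-normalisation statistics noisy: training loss can fall by exploiting
  batch composition while held-out loss rises, and early stopping then
  freezes the model near the majority/mean predictor. The convolutional
  prior suits contiguous multi-marker structure; isolated single-marker
  signals are learned far more reliably by the tree families and the DNN —
  consistent with the general pattern that tree ensembles dominate small
  tabular SNP panels.
* The scan is single-marker; kinship mixed models and pseudo-QTN iteration
  are out of scope, so close linkage to a true locus inflates neighbouring
  hits the way any marginal scan does.
* Multi-allelic sites, indels, phasing and imputation are not supported.
* The two-locus categorical mixing rule is not a genetic interaction model.
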