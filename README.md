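# gsbench

Genomic selection studies ask whether genome-wide SNP genotypes can predict
a line's phenotype well enough to drive breeding decisions — and, just as
importantly, *which* markers carry the signal, so that genotyping panels can
be cut from millions of SNPs to a few targeted regions. `gsbench` packages
that whole workflow for R users working on diversity panels (the motivating
setting is crop accessions with biallelic SNP calls in VCF and categorical
or continuous trait records):

1. **Preprocessing** — VCF import, exclusion of lines with over 1% missing
   calls, SNP filters (MAF ≥ 0.05, missing rate < 10%), 1-in-20 sequential
   thinning, and one-hot encoding of genotype classes with an invertible
   feature index.
2. **Model benchmarking** — XGBoost (optionally tuned by sequential
   model-based search over the standard hyperparameter bounds), random
   forest (100 trees, √p feature subsampling), and in-package convolutional
   and dense neural networks (Adamax, lr 0.003, batch = n/50), each under
   10-fold cross-validation with best-fold selection and a 20% holdout.
   Classification is scored as accuracy (%), regression as RMSE as a
   percentage of the trait mean.
3. **Interpretation** — gain-based feature ranking of the fitted XGBoost
   model; top-20 SNPs chained into Regions of Importance (ROIs): ≥ 3
   distinct SNPs whose nearest-neighbour gaps are ≤ 100 kbp.
4. **GWAS cross-check** — a single-marker scan with 3 principal-component
   covariates and a 0.05/m significance threshold (a documented stand-in
   for FarmCPU-style pseudo-QTN methods), plus ROI ↔ significant-locus
   overlap reports.
5. **Reduction** — ROI-guided marker-panel extraction and re-benchmarking
   on the reduced input.

A synthetic genotype/phenotype generator (LD blocks, tunable MAF spectrum
and heritability, near-Mendelian and polygenic traits) makes every stage
testable without external data.

## Worked example

```r
library(gsbench)

# simulate a small panel: 300 lines x 200 SNPs on 2 chromosomes
map <- simulate_genome_map(n_chrom = 2, snps_per_chrom = 100,
                           chrom_length_bp = 2e6, seed = 7)
tab <- simulate_genotypes(map, sim_config(n_lines = 300, seed = 3))
tab
#> genotype_table: 300 lines x 200 SNPs on 2 chromosome(s)
#>   missing calls: 0.467%

# a fully penetrant dominant trait at one locus
causal <- map$id[10]
tm  <- trait_model("monogenic-categorical",
                   setNames(list(dominant_penetrance(1)), causal))
ph  <- simulate_categorical_trait(tab, tm, seed = 5)

# encode, split, cross-validate XGBoost, evaluate on the holdout
fm   <- one_hot_encode(tab)
sp   <- holdout_split(tab$line_ids, 0.2, seed = 9)
y    <- ph$value[match(tab$line_ids, ph$line_id)]
tr   <- match(sp$train_line_ids, tab$line_ids)
ho   <- match(sp$holdout_line_ids, tab$line_ids)
fit  <- crossval_fit("XGB", fm$values[tr, ], y[tr], task_for_phenotype(ph),
                     cv = cv_config(5, seed = 2))
evaluate(fit, fm$values[ho, ], y[ho])$holdout_score
#> [1] 100

# interpret: the top-ranked feature decodes to the causal SNP
rank_features_by_gain(fit, fm)[1, c("rank", "snp_id", "class", "gain")]
#>   rank          snp_id   class gain
#> 1    1 chr01_000250105 REF_HOM    1
causal
#> [1] "chr01_000250105"
```

A holdout accuracy of 100 and the causal marker at rank 1 are what a fully
penetrant monogenic trait should give; on polygenic traits the ranking
spreads over the causal cluster and `cluster_rois()` turns it into genomic
intervals for `extract_regions()`.

`run_full_experiment()` wires all stages together (simulate or load →
preprocess → train → interpret → GWAS → reduce → retrain → compare) under a
single master seed; `inst/cli/gsbench.R` exposes the same stages as shell
subcommands (`simulate`, `preprocess`, `train`, `interpret`, `gwas`,
`reduce`, `compare`, `run-all`).

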