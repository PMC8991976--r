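# Orchestration of the full experiment: simulate (or load) -> preprocess ->
# train on the full input -> interpret the XGBoost model into ROIs -> GWAS
# cross-check -> reduce the input to target regions -> retrain -> compare.

# fixed per-stage seed offsets derived from the master seed, so each stage
# is independently reproducible
.stage_seed <- function(master, stage) {
  offs <- c(map = 11L, genotypes = 23L, trait = 101L, split = 211L,
            cv = 307L, tune = 401L, gwas = 503L, reduced_split = 601L)
  (as.integer(master) + offs[[stage]]) %% .Machine$integer.max
}

#' Experiment configuration
#'
#' Bundles every stage's parameters. Either `vcf_path`/`phenotype_paths`
#' (load real data) or the simulation block (`map` + `sim` + `traits`) must
#' be given.
#'
#' @param sim a [sim_config()] (seed inside it is overridden by the master
#'   seed discipline).
#' @param map_params list(n_chrom, snps_per_chrom, chrom_length_bp) for
#'   [simulate_genome_map()].
#' @param traits named list; each element is a [trait_model()].
#' @param vcf_path,phenotype_paths optional real-data inputs replacing the
#'   simulation block (`phenotype_paths` named by trait).
#' @param line_max_missing,maf_min,snp_max_missing,keep_every preprocessing
#'   parameters (defaults 0.01, 0.05, 0.10, 20).
#' @param holdout_fraction holdout fraction (default 0.2).
#' @param cv_k cross-validation folds (default 10).
#' @param tune optional [tune_space()]; `NULL` (default) trains XGBoost at
#'   its default settings.
#' @param top_n,max_gap_bp,min_roi_size,flank_bp,fallback_window_bp ROI
#'   parameters.
#' @param scan a [scan_config()].
#' @param include_dl train the CNN/DNN families too (default TRUE); when
#'   FALSE the comparison covers XGB and RF only and the report says so.
#' @param nn_epochs epoch cap for the CNN/DNN families.
#' @param seed master seed; all stage seeds derive from it by fixed offsets.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              map_params = list(n_chrom = 2L,
                                                snps_per_chrom = 250L,
                                                chrom_length_bp = 5e6),
                              traits = NULL,
                              vcf_path = NULL, phenotype_paths = NULL,
                              line_max_missing = 0.01, maf_min = 0.05,
                              snp_max_missing = 0.10, keep_every = 1L,
                              holdout_fraction = 0.2, cv_k = 10L,
                              tune = NULL,
                              top_n = 20L, max_gap_bp = 100000L,
                              min_roi_size = 3L, flank_bp = 0L,
                              fallback_window_bp = 250000L,
                              scan = scan_config(),
                              include_dl = TRUE, nn_epochs = 200L,
                              seed = 1L) {
  if (is.null(vcf_path) && is.null(traits))
    stop("either a vcf_path or a simulated trait list is required")
  structure(as.list(environment()), class = "experiment_config")
}

.load_or_simulate <- function(cfg) {
  if (!is.null(cfg$vcf_path)) {
    table <- read_vcf_to_table(cfg$vcf_path)
    phenos <- lapply(cfg$phenotype_paths, read_phenotypes)
    names(phenos) <- names(cfg$phenotype_paths)
    return(list(table = table, phenos = phenos, simulated = FALSE))
  }
  map <- do.call(simulate_genome_map,
                 c(cfg$map_params, list(seed = .stage_seed(cfg$seed, "map"))))
  sim <- cfg$sim
  sim$seed <- .stage_seed(cfg$seed, "genotypes")
  table <- simulate_genotypes(map, sim)
  phenos <- list()
  for (i in seq_along(cfg$traits)) {
    tm <- cfg$traits[[i]]
    nm <- names(cfg$traits)[i]
    sd <- (.stage_seed(cfg$seed, "trait") + i) %% .Machine$integer.max
    phenos[[nm]] <- if (tm$kind == "polygenic-continuous")
      simulate_continuous_trait(table, tm, seed = sd, trait_name = nm)
    else simulate_categorical_trait(table, tm, seed = sd, trait_name = nm)
  }
  list(table = table, phenos = phenos, simulated = TRUE)
}

.preprocess <- function(table, cfg) {
  n0_lines <- length(table$line_ids); n0_snps <- nrow(table$snp_map)
  t1 <- filter_lines(table, cfg$line_max_missing)
  t2 <- filter_snps(t1, cfg$maf_min, cfg$snp_max_missing)
  t3 <- thin_sequential(t2, cfg$keep_every)
  prov <- data.frame(
    stage = c("input", "filter_lines", "filter_snps", "thin_sequential"),
    n_lines = c(n0_lines, length(t1$line_ids), length(t2$line_ids),
                length(t3$line_ids)),
    n_snps = c(n0_snps, nrow(t1$snp_map), nrow(t2$snp_map), nrow(t3$snp_map)),
    removed = c(0L, attr(t1, "n_removed"),
                attr(t2, "n_removed"), nrow(t2$snp_map) - nrow(t3$snp_map)))
  list(table = t3, provenance = prov)
}

.families_for <- function(cfg) {
  if (cfg$include_dl) c("XGB", "RF", "CNN", "DNN") else c("XGB", "RF")
}

# train all configured families on one trait/table; returns metrics rows and
# the XGB cv_fit (for interpretation)
.train_trait <- function(table, pheno, cfg, dataset, trait_name) {
  ttype <- trait_type(pheno)
  task <- task_for_phenotype(pheno)
  class_labels <- attr(pheno, "class_labels")
  y_all <- pheno$value[match(table$line_ids, pheno$line_id)]
  stopifnot(!anyNA(match(table$line_ids, pheno$line_id)))
  ref_mean <- if (ttype == "continuous") mean(y_all) else NA_real_
  split <- holdout_split(table$line_ids, cfg$holdout_fraction,
                         seed = .stage_seed(cfg$seed, "split"))
  fm <- one_hot_encode(table)
  x <- fm$values
  tr <- split$train_line_ids; ho <- split$holdout_line_ids
  y_tr <- y_all[match(tr, table$line_ids)]
  y_ho <- y_all[match(ho, table$line_ids)]
  xgb_params <- list()
  if (!is.null(cfg$tune)) {
    sp <- cfg$tune
    sp$seed <- .stage_seed(cfg$seed, "tune")
    y_enc <- .encode_labels(y_tr, task, class_labels)
    xgb_params <- tune_xgboost(x[tr, , drop = FALSE], y_enc, sp,
                               task)$best_params
  }
  rows <- list(); xgb_fit <- NULL
  for (fam in .families_for(cfg)) {
    if (fam == "CNN" && ncol(x) < cnn_min_features()) {
      message("skipping CNN for ", trait_name, ": ", ncol(x),
              " features is below the CNN minimum of ", cnn_min_features())
      next
    }
    fit <- crossval_fit(fam, x[tr, , drop = FALSE], y_tr, task,
                        cv = cv_config(cfg$cv_k, .stage_seed(cfg$seed, "cv")),
                        class_labels = class_labels,
                        xgb_params = if (fam == "XGB") xgb_params else list(),
                        nn_epochs = cfg$nn_epochs)
    met <- evaluate(fit, x[ho, , drop = FALSE], y_ho,
                    reference_mean = ref_mean)
    rows[[fam]] <- data.frame(trait = trait_name, dataset = dataset,
                              family = fam, metric_type = met$metric_type,
                              value = met$holdout_score,
                              best_fold_score = met$fold_scores[fit$best_fold],
                              stringsAsFactors = FALSE)
    if (fam == "XGB") xgb_fit <- fit
  }
  list(metrics = do.call(rbind, rows), xgb_fit = xgb_fit,
       feature_matrix = fm, split = split, ref_mean = ref_mean)
}

#' Run the full experiment
#'
#' Executes all stages for every configured trait: preprocessing, full-input
#' training of the configured model families, gain-based ROI extraction from
#' the full-input XGBoost model, a PC-adjusted association scan of the
#' preprocessed markers, ROI/SAL overlap, region-guided input reduction, and
#' reduced-input re-training. Deterministic per master seed for the
#' tree-based stages; the neural families are deterministic to the engine's
#' own guarantees.
#'
#' @param cfg an [experiment_config()].
#' @return list of class `experiment_report` with `config`, `provenance`,
#'   `metrics` (full + reduced rows), `rois`, `regions`, `retained_fraction`,
#'   `gwas` (per-trait results/SALs/overlap), `comparison`, `tally`.
#' @export
run_full_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  data <- .load_or_simulate(cfg)
  prep <- .preprocess(data$table, cfg)
  table <- prep$table
  dosage <- dosage_matrix(table, "mean")
  pcs <- compute_pcs(dosage, cfg$scan$n_pcs)
  metrics <- list(); rois <- list(); regions <- list()
  retained <- list(); gwas <- list()
  for (nm in names(data$phenos)) {
    pheno <- data$phenos[[nm]]
    pheno <- pheno[pheno$line_id %in% table$line_ids, ]
    full <- .train_trait(table, pheno, cfg, "full", nm)
    metrics[[paste0(nm, ".full")]] <- full$metrics
    ranked <- rank_features_by_gain(full$xgb_fit, full$feature_matrix,
                                    top_n = cfg$top_n)
    roi <- cluster_rois(ranked, cfg$max_gap_bp, cfg$min_roi_size)
    rois[[nm]] <- roi
    reg <- define_target_regions(roi, ranked, cfg$flank_bp,
                                 cfg$fallback_window_bp)
    regions[[nm]] <- reg
    y_vec <- pheno$value[match(table$line_ids, pheno$line_id)]
    scan_res <- assoc_scan(table, pheno, covariates = pcs)
    sal <- significant_loci(scan_res, cfg$scan)
    gwas[[nm]] <- list(results = scan_res, sal = sal,
                       overlap = overlap_roi_sal(roi, sal))
    red_table <- extract_regions(table, reg)
    retained[[nm]] <- attr(red_table, "retained_fraction")
    red <- .train_trait(red_table, pheno, cfg, "reduced", nm)
    metrics[[paste0(nm, ".reduced")]] <- red$metrics
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  # the comparison covers the families scored in every trait x dataset cell
  # (the CNN is skipped when a reduced panel falls below its receptive field)
  cell <- paste(metrics$trait, metrics$dataset)
  common <- Reduce(intersect, split(metrics$family, cell))
  comparison <- compare_models(metrics[metrics$family %in% common, ])
  structure(list(config = cfg, provenance = prep$provenance,
                 n_families = length(.families_for(cfg)),
                 dl_included = cfg$include_dl,
                 metrics = metrics, rois = rois, regions = regions,
                 retained_fraction = unlist(retained), gwas = gwas,
                 comparison = comparison, tally = comparison$tally),
            class = "experiment_report")
}

#' Best-model tallies from full- and reduced-input metrics
#'
#' Counts, per trait x dataset cell, the family with the best holdout
#' metric (highest accuracy or lowest error; ties to the earlier family in
#' XGB, RF, CNN, DNN order), and totals per family over the 2 x n_traits
#' cells.
#'
#' @param full,reduced metric data.frames (columns `trait`, `family`,
#'   `metric_type`, `value`) or [run_full_experiment()] reports; both must
#'   cover the same traits.
#' @return list with `per_cell` (best family per trait x dataset) and
#'   `totals` (named counts summing to the number of cells).
#' @export
summarize_best_models <- function(full, reduced) {
  get_metrics <- function(x, ds) {
    if (inherits(x, "experiment_report")) x <- x$metrics[x$metrics$dataset == ds, ]
    x$dataset <- ds
    x
  }
  full <- get_metrics(full, "full")
  reduced <- get_metrics(reduced, "reduced")
  if (!setequal(unique(full$trait), unique(reduced$trait)))
    stop("full and reduced reports cover different trait lists")
  fams <- intersect(c("XGB", "RF", "CNN", "DNN"), unique(full$family))
  both <- rbind(full[, c("trait", "dataset", "family", "metric_type", "value")],
                reduced[, c("trait", "dataset", "family", "metric_type", "value")])
  cells <- unique(both[, c("trait", "dataset")])
  best <- vapply(seq_len(nrow(cells)), function(i) {
    sub <- both[both$trait == cells$trait[i] & both$dataset == cells$dataset[i], ]
    sub <- sub[match(fams, sub$family), ]
    v <- if (sub$metric_type[1] == "accuracy_pct") sub$value else -sub$value
    fams[which.max(v)]
  }, character(1))
  totals <- vapply(fams, function(f) sum(best == f), numeric(1))
  list(per_cell = data.frame(cells, best_family = best, stringsAsFactors = FALSE),
       totals = totals)
}

#' Write the experiment report
#'
#' Emits the metric table as TSV and a small markdown summary (per-family
#' holdout metrics for full and reduced inputs, best-model tallies, ROI and
#' SAL counts, retained-SNP fractions).
#'
#' @param report an [run_full_experiment()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$metrics, file.path(dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$provenance, file.path(dir, "provenance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  md <- c("# Experiment report", "",
          if (!report$dl_included)
            "Deep-learning families were disabled; comparisons cover XGB and RF only.",
          "", "## Best-model tally",
          paste0("- ", names(report$tally), ": ", report$tally), "",
          "## Retained SNP fraction per trait (reduced input)",
          paste0("- ", names(report$retained_fraction), ": ",
                 sprintf("%.1f%%", 100 * report$retained_fraction)), "",
          "## ROI / SAL counts",
          vapply(names(report$rois), function(nm) {
            paste0("- ", nm, ": ", nrow(report$rois[[nm]]), " ROI(s), ",
                   nrow(report$gwas[[nm]]$sal), " SAL(s), ",
                   report$gwas[[nm]]$overlap$n_rois_with_sal,
                   " ROI(s) with a SAL")
          }, character(1)))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
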