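test_that("metric identities hold exactly", {
  expect_equal(accuracy_percent(c(1, 1, 0), c(1, 1, 0)), 100)
  expect_equal(accuracy_percent(c(1, 0, 1, 1, 0, 0), c(1, 0, 1, 0, 1, 0)),
               100 * 4 / 6)
  expect_error(accuracy_percent(numeric(), numeric()), "empty")

  expect_equal(rmse_percent_of_mean(c(1, 2, 3), c(1, 2, 3)), 0)
  # truths (10,20,30), predictions (20,20,20), reference mean 20:
  # RMSE = sqrt(200/3) = 8.1650 -> 40.82%
  expect_equal(rmse_percent_of_mean(c(20, 20, 20), c(10, 20, 30), 20),
               100 * sqrt(200 / 3) / 20, tolerance = 1e-12)
  expect_equal(round(rmse_percent_of_mean(c(20, 20, 20), c(10, 20, 30), 20), 2),
               40.82)
  # constant-at-mean predictor equals 100 * population SD / mean
  set.seed(8)
  y <- rnorm(57, 10, 3)
  expect_equal(rmse_percent_of_mean(rep(mean(y), length(y)), y),
               100 * sqrt(mean((y - mean(y))^2)) / mean(y), tolerance = 1e-12)
  expect_error(rmse_percent_of_mean(1, 1, reference_mean = 0), "zero")
})

test_that("fold assignment partitions samples; stratified folds balance classes", {
  y <- sample(rep(c("a", "b", "c"), times = c(40, 30, 20)))
  folds <- make_folds(y, 10, stratified = TRUE, seed = 3)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), length(y))
  for (cl in c("a", "b", "c")) {
    per_fold <- table(factor(folds[y == cl], levels = 1:10))
    expect_lte(diff(range(per_fold)), 1)  # within one sample of balance
  }
  expect_identical(folds, make_folds(y, 10, stratified = TRUE, seed = 3))
})

test_that("crossval_fit keeps the best fold and guards the contracts", {
  setup <- monogenic_setup(n_lines = 120, n_snps = 30, seed = 23)
  fm <- one_hot_encode(setup$table)
  y <- pheno_vector(setup$pheno, setup$table)
  task <- task_for_phenotype(setup$pheno)
  fit <- crossval_fit("XGB", fm$values, y, task, cv = cv_config(5, 11))
  expect_length(fit$fold_scores, 5)
  expect_equal(fit$fold_scores[fit$best_fold], max(fit$fold_scores))
  expect_equal(sort(unique(fit$folds)), 1:5)

  # regression selects the minimum-RMSE fold
  tabc <- setup$table
  tm <- trait_model("polygenic-continuous",
                    data.frame(snp = setup$causal, effect = 1),
                    heritability = 0.6)
  phc <- simulate_continuous_trait(tabc, tm, seed = 31)
  fitr <- crossval_fit("RF", fm$values, pheno_vector(phc, tabc),
                       task_spec("regression"), cv = cv_config(5, 12))
  expect_equal(fitr$fold_scores[fitr$best_fold], min(fitr$fold_scores))

  # a class with fewer members than k errors, naming the class
  y_rare <- y; y_rare[1] <- "rareclass"
  expect_error(
    crossval_fit("XGB", fm$values, y_rare, task_spec("multiclass", 3),
                 cv = cv_config(10, 1)),
    "rareclass")
  expect_error(crossval_fit("XGB", fm$values[1:4, ], y[1:4], task,
                            cv = cv_config(10, 1)), "smaller than k")
})

test_that("evaluate blocks train/holdout leakage and scores the holdout", {
  setup <- monogenic_setup(n_lines = 150, n_snps = 30, seed = 29)
  fm <- one_hot_encode(setup$table)
  y <- pheno_vector(setup$pheno, setup$table)
  sp <- holdout_split(setup$table$line_ids, 0.2, seed = 4)
  tr <- sp$train_line_ids
  task <- task_for_phenotype(setup$pheno)
  fit <- crossval_fit("XGB", fm$values[tr, ], y[match(tr, setup$table$line_ids)],
                      task, cv = cv_config(5, 2))
  ho <- sp$holdout_line_ids
  met <- evaluate(fit, fm$values[ho, , drop = FALSE],
                  y[match(ho, setup$table$line_ids)])
  expect_s3_class(met, "gs_metrics")
  expect_gte(met$holdout_score, 0); expect_lte(met$holdout_score, 100)

  leaky <- c(ho[-1], tr[1])
  expect_error(evaluate(fit, fm$values[leaky, , drop = FALSE],
                        y[match(leaky, setup$table$line_ids)]), "overlap")
  expect_error(evaluate(fit, fm$values[0, , drop = FALSE], y[0]), "empty")
})

test_that("XGB and RF cross-validation is bit-reproducible under a fixed seed", {
  setup <- monogenic_setup(n_lines = 100, n_snps = 25, seed = 37)
  fm <- one_hot_encode(setup$table)
  y <- pheno_vector(setup$pheno, setup$table)
  task <- task_for_phenotype(setup$pheno)
  for (fam in c("XGB", "RF")) {
    f1 <- crossval_fit(fam, fm$values, y, task, cv = cv_config(5, 21))
    f2 <- crossval_fit(fam, fm$values, y, task, cv = cv_config(5, 21))
    expect_identical(f1$fold_scores, f2$fold_scores)
    p1 <- gsbench:::.predict_family(fam, f1$fitted, fm$values, task)
    p2 <- gsbench:::.predict_family(fam, f2$fitted, fm$values, task)
    expect_identical(p1, p2)
  }
})

test_that("tuned configurations stay inside their bounds and help on a monogenic trait", {
  setup <- monogenic_setup(n_lines = 120, n_snps = 25, seed = 43)
  fm <- one_hot_encode(setup$table)
  y <- pheno_vector(setup$pheno, setup$table)
  task <- task_for_phenotype(setup$pheno)
  y_enc <- gsbench:::.encode_labels(y, task, sort(unique(y)))

  sp1 <- tune_space(n_search_iterations = 1, seed = 5)
  r1 <- tune_xgboost(fm$values, y_enc, sp1, task)
  expect_equal(nrow(r1$history), 1)

  sp <- tune_space(n_search_iterations = 8, seed = 5)
  res <- tune_xgboost(fm$values, y_enc, sp, task)
  for (nm in names(sp$bounds)) {
    b <- sp$bounds[[nm]]
    expect_gte(res$best_params[[nm]], b[1])
    expect_lte(res$best_params[[nm]], b[2])
  }
  # tuned model at least as good as defaults minus tolerance (same folds)
  default_cv <- gsbench:::.inner_cv_score(fm$values, y_enc, task, list(), 3, 5)
  expect_gte(res$best_score, default_cv - 2)

  expect_error(tune_xgboost(fm$values, rep(0L, nrow(fm$values)), sp, task),
               "one class")
})

test_that("compare_models reproduces hand-computed differences and tallies", {
  # toy: XGB (90,80), CNN (85,70), DNN (80,75) -> XGB-DL = mean(7.5, 7.5) = 7.5
  toy <- expand.grid(trait = c("t1", "t2"),
                     family = c("XGB", "RF", "CNN", "DNN"),
                     stringsAsFactors = FALSE)
  vals <- c(t1.XGB = 90, t2.XGB = 80, t1.RF = 88, t2.RF = 78,
            t1.CNN = 85, t2.CNN = 70, t1.DNN = 80, t2.DNN = 75)
  toy$value <- vals[paste(toy$trait, toy$family, sep = ".")]
  toy$metric_type <- "accuracy_pct"
  cs <- compare_models(toy)
  expect_equal(cs$differences$mean_difference[
    cs$differences$comparison == "XGB-DL"], 7.5)
  expect_equal(sum(cs$tally), 2)
  expect_equal(unname(cs$tally["XGB"]), 2)

  # identical metrics: zero differences, ties resolved to XGB and logged
  tied <- toy; tied$value <- 50
  ct <- compare_models(tied)
  expect_true(all(ct$differences$mean_difference == 0))
  expect_equal(unname(ct$tally["XGB"]), 2)
  expect_length(ct$ties, 2)

  # a family scored for one trait but absent for another is a missing cell
  expect_error(compare_models(toy[!(toy$family == "DNN" & toy$trait == "t2"), ]),
               "missing family")
  # dropping a family everywhere is a legal smaller comparison (no DL run)
  no_dl <- compare_models(toy[!toy$family %in% c("CNN", "DNN"), ])
  expect_equal(sum(no_dl$tally), 2)
  expect_equal(nrow(no_dl$differences), 0)
})

test_that("best-model tallies over 7 traits x 2 datasets sum to 14", {
  set.seed(61)
  grid <- expand.grid(trait = paste0("tr", 1:7),
                      family = c("XGB", "RF", "CNN", "DNN"),
                      dataset = c("full", "reduced"),
                      stringsAsFactors = FALSE)
  grid$value <- runif(nrow(grid), 50, 100)
  grid$metric_type <- "accuracy_pct"
  cs <- compare_models(grid)
  expect_equal(sum(cs$tally), 14)
})

test_that("compare_models matches a brute-force recomputation on fuzzed tables", {
  for (s in 1:200) {
    set.seed(s)
    n_tr <- sample(2:5, 1)
    mt <- sample(c("accuracy_pct", "rmse_pct_of_mean"), 1)
    grid <- expand.grid(trait = paste0("t", seq_len(n_tr)),
                        family = c("XGB", "RF", "CNN", "DNN"),
                        stringsAsFactors = FALSE)
    grid$value <- round(runif(nrow(grid), 0, 100), 1)
    grid$metric_type <- mt
    cs <- compare_models(grid)
    # brute force: per trait best family; XGB-DL difference by direct means
    better <- if (mt == "accuracy_pct") which.max else which.min
    fams <- c("XGB", "RF", "CNN", "DNN")
    tally_bf <- setNames(rep(0, 4), fams)
    xgb_dl <- numeric(n_tr)
    for (ti in seq_len(n_tr)) {
      sub <- grid[grid$trait == paste0("t", ti), ]
      v <- sub$value[match(fams, sub$family)]
      tally_bf[better(v)] <- tally_bf[better(v)] + 1
      xgb_dl[ti] <- v[1] - mean(v[3:4])
    }
    expect_equal(unname(cs$tally), unname(tally_bf))
    expect_equal(cs$differences$mean_difference[
      cs$differences$comparison == "XGB-DL"], mean(xgb_dl))
  }
})

test_that("tree models reach high holdout accuracy on a degenerate monogenic trait", {
  setup <- monogenic_setup(n_lines = 300, n_snps = 100, seed = 53)
  fm <- one_hot_encode(setup$table)
  y <- pheno_vector(setup$pheno, setup$table)
  task <- task_for_phenotype(setup$pheno)
  sp <- holdout_split(setup$table$line_ids, 0.2, seed = 6)
  tr <- sp$train_line_ids; ho <- sp$holdout_line_ids
  ti <- match(tr, setup$table$line_ids); hi <- match(ho, setup$table$line_ids)
  for (fam in c("XGB", "RF")) {
    fit <- crossval_fit(fam, fm$values[ti, ], y[ti], task, cv = cv_config(10, 7))
    met <- evaluate(fit, fm$values[hi, , drop = FALSE], y[hi])
    expect_gte(met$holdout_score, 95)
  }
})

test_that("all families fall back to the trait-mean baseline at zero heritability", {
  map <- simulate_genome_map(1, 40, 2e6, seed = 59)
  tab <- simulate_genotypes(map, sim_config(n_lines = 1000, missing_rate = 0,
                                            seed = 60))
  tm <- trait_model("polygenic-continuous",
                    data.frame(snp = map$id[c(10, 30)], effect = c(1, -1)),
                    heritability = 0)
  ph <- simulate_continuous_trait(tab, tm, seed = 61)
  fm <- one_hot_encode(tab)
  y <- pheno_vector(ph, tab)
  ref_mean <- mean(y)
  sp <- holdout_split(tab$line_ids, 0.2, seed = 8)
  ti <- match(sp$train_line_ids, tab$line_ids)
  hi <- match(sp$holdout_line_ids, tab$line_ids)
  baseline <- rmse_percent_of_mean(rep(mean(y[ti]), length(hi)), y[hi], ref_mean)
  task <- task_spec("regression")
  # XGBoost enters the benchmark tuned, as the pipeline prescribes; on a null
  # trait the search selects regularised configurations
  tuned <- tune_xgboost(fm$values[ti, ], y[ti],
                        tune_space(n_search_iterations = 15, seed = 3), task)
  for (fam in c("XGB", "RF", "CNN", "DNN")) {
    fit <- crossval_fit(fam, fm$values[ti, ], y[ti], task,
                        cv = cv_config(5, 9),
                        xgb_params = if (fam == "XGB") tuned$best_params
                                     else list())
    met <- evaluate(fit, fm$values[hi, , drop = FALSE], y[hi],
                    reference_mean = ref_mean)
    expect_lt(abs(met$holdout_score - baseline) / baseline, 0.10)
  }
})
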