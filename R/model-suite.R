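# The four benchmarked model families — XGBoost, random forest, and the
# in-package convolutional and dense networks — behind one interface:
# build_model() -> crossval_fit() -> evaluate(), plus Bayesian
# hyperparameter search for XGBoost and the cross-model comparison summary.

#' Task specification
#'
#' @param trait_type `"binary"`, `"multiclass"` or `"regression"`
#'   (`"continuous"` is accepted as an alias for regression).
#' @param n_classes number of classes, required for multiclass (>= 3).
#' @return list of class `task_spec`.
#' @export
task_spec <- function(trait_type, n_classes = NULL) {
  if (trait_type == "continuous") trait_type <- "regression"
  stopifnot(trait_type %in% c("binary", "multiclass", "regression"))
  if (trait_type == "multiclass") {
    if (is.null(n_classes) || n_classes < 3)
      stop("multiclass task needs n_classes >= 3")
  }
  structure(list(trait_type = trait_type, n_classes = n_classes),
            class = "task_spec")
}

#' Task spec matching a phenotype table
#' @param pheno a [phenotype_table()].
#' @return a [task_spec()].
#' @export
task_for_phenotype <- function(pheno) {
  tt <- trait_type(pheno)
  if (tt == "continuous") task_spec("regression")
  else task_spec(tt, n_classes = length(attr(pheno, "class_labels")))
}

# Fixed architecture constants of the four families.
.arch_constants <- list(
  CNN = list(filters = c(12L, 10L, 8L), kernels = c(14L, 10L, 8L),
             dropout = c(0.20, 0.10), pool = 2L,
             dense = c(48L, 32L, 16L)),
  DNN = list(dense = c(200L, 100L, 64L, 32L, 16L),
             dropout = c(0.03, 0.02, 0.01)),
  RF = list(n_trees = 100L, max_features = "sqrt"),
  XGB = list(n_estimators = 100L),
  optimizer = list(name = "adamax", learning_rate = 0.003),
  batch_size_divisor = 50L)

#' Architecture specification for a model family
#'
#' Returns the fixed architecture constants for one of the four families.
#' CNN: three 1D ReLU convolutions (12/10/8 filters, kernels 14/10/8) with
#' 20\% dropout between stages 1-2 and 10\% between 2-3, a size-2 max pool
#' and batch normalisation, then ReLU dense layers of 48/32/16 nodes each
#' followed by batch normalisation. DNN: ReLU dense layers of
#' 200/100/64/32/16 nodes with dropouts of 3/2/1\% after the first three and
#' batch normalisation after the final dense layer. Both train with Adamax
#' at learning rate 0.003 and a batch size of 1/50th of the training
#' samples. RF: 100 trees with square-root feature subsampling. The output
#' head is 1 linear node (regression), 1 sigmoid node (binary) or
#' `n_classes` softmax nodes (multiclass).
#'
#' @param family `"XGB"`, `"RF"`, `"CNN"` or `"DNN"`.
#' @return list of class `arch_spec`.
#' @export
arch_spec <- function(family = c("XGB", "RF", "CNN", "DNN")) {
  family <- match.arg(family)
  structure(c(list(family = family), .arch_constants[[family]],
              optimizer = list(.arch_constants$optimizer),
              batch_size_divisor = .arch_constants$batch_size_divisor),
            class = "arch_spec")
}

#' Batch size rule
#'
#' One fiftieth of the training-sample count, floored, never below 1.
#' @param n_train number of training samples.
#' @return integer batch size.
#' @export
batch_size_for <- function(n_train) max(1L, as.integer(n_train) %/% 50L)

#' Minimum input length of the CNN
#'
#' The three valid-padding convolutions and the size-2 max pool shrink the
#' sequence; the input must be long enough that at least one pooled position
#' survives.
#' @return integer minimum feature count.
#' @export
cnn_min_features <- function() {
  k <- .arch_constants$CNN$kernels
  sum(k - 1L) + .arch_constants$CNN$pool
}

#' Build an untrained model
#'
#' @param arch an [arch_spec()] (or family string).
#' @param task a [task_spec()].
#' @param n_features number of input features (one-hot columns). The CNN
#'   consumes them as a single-channel 1D sequence in genome order and
#'   requires at least [cnn_min_features()] features.
#' @return list of class `gs_model` with the family, task and (for CNN/DNN)
#'   the constructed network.
#' @export
build_model <- function(arch, task, n_features) {
  if (is.character(arch)) arch <- arch_spec(arch)
  stopifnot(inherits(arch, "arch_spec"), inherits(task, "task_spec"))
  n_out <- switch(task$trait_type, regression = 1L, binary = 1L,
                  multiclass = as.integer(task$n_classes))
  net <- NULL
  if (arch$family == "CNN") {
    if (n_features < cnn_min_features())
      stop("CNN requires at least ", cnn_min_features(),
           " input features; got ", n_features)
    f <- arch$filters; k <- arch$kernels
    len <- n_features
    layers <- list(nn_conv1d(k[1], 1L, f[1]))
    len <- len - k[1] + 1L
    layers <- c(layers, list(nn_dropout(arch$dropout[1]),
                             nn_conv1d(k[2], f[1], f[2])))
    len <- len - k[2] + 1L
    layers <- c(layers, list(nn_dropout(arch$dropout[2]),
                             nn_conv1d(k[3], f[2], f[3])))
    len <- len - k[3] + 1L
    layers <- c(layers, list(nn_maxpool1d(arch$pool)))
    len <- len %/% arch$pool
    layers <- c(layers, list(nn_batchnorm(f[3]), nn_flatten()))
    width <- len * f[3]
    for (d in arch$dense) {
      layers <- c(layers, list(nn_dense(width, d, "relu"), nn_batchnorm(d)))
      width <- d
    }
    layers <- c(layers, list(nn_dense(width, n_out, "linear")))
    net <- list(layers = layers, input_rank = 3L, task = task$trait_type,
                n_classes = n_out)
  } else if (arch$family == "DNN") {
    width <- n_features
    layers <- list()
    for (i in seq_along(arch$dense)) {
      layers <- c(layers, list(nn_dense(width, arch$dense[i], "relu")))
      width <- arch$dense[i]
      if (i <= length(arch$dropout))
        layers <- c(layers, list(nn_dropout(arch$dropout[i])))
    }
    layers <- c(layers, list(nn_batchnorm(width),
                             nn_dense(width, n_out, "linear")))
    net <- list(layers = layers, input_rank = 2L, task = task$trait_type,
                n_classes = n_out)
  }
  structure(list(family = arch$family, arch = arch, task = task,
                 n_features = as.integer(n_features), net = net,
                 trained = FALSE),
            class = "gs_model")
}

#' XGBoost hyperparameter search space
#'
#' Named bounds for the Bayesian search; parameters marked log-scale are
#' searched on log10. The lower bounds of reg_lambda, reg_alpha and gamma
#' are 1e-9 and of scale_pos_weight 1e-6.
#'
#' @param n_search_iterations number of search evaluations (default 25).
#' @param seed integer seed for the search.
#' @return list of class `tune_space` with `bounds`, `log_scale`,
#'   `integer_params`, `n_search_iterations`, `seed`.
#' @export
tune_space <- function(n_search_iterations = 25L, seed = 1L) {
  bounds <- list(
    learning_rate    = c(0.01, 1.0),
    min_child_weight = c(0, 10),
    max_depth        = c(0, 50),
    max_delta_step   = c(0, 20),
    subsample        = c(0.01, 1.0),
    colsample_bytree = c(0.01, 1.0),
    colsample_bylevel = c(0.01, 1.0),
    reg_lambda       = c(1e-9, 1000),
    reg_alpha        = c(1e-9, 1.0),
    gamma            = c(1e-9, 0.5),
    n_estimators     = c(50, 200),
    scale_pos_weight = c(1e-6, 500))
  structure(list(bounds = bounds,
                 log_scale = c("reg_lambda", "reg_alpha", "gamma",
                               "scale_pos_weight"),
                 integer_params = c("max_depth", "max_delta_step",
                                    "n_estimators"),
                 n_search_iterations = as.integer(n_search_iterations),
                 seed = as.integer(seed)),
            class = "tune_space")
}

.xgb_objective <- function(task) {
  switch(task$trait_type,
    regression = list(objective = "reg:squarederror"),
    binary = list(objective = "binary:logistic"),
    multiclass = list(objective = "multi:softprob",
                      num_class = as.integer(task$n_classes)))
}

.xgb_fit <- function(x, y, task, params = list(), seed = 1L) {
  obj <- .xgb_objective(task)
  n_rounds <- params$n_estimators %||% .arch_constants$XGB$n_estimators
  params$n_estimators <- NULL
  # max_depth 0 means unlimited depth; xgboost requires it only for hist
  if (!is.null(params$max_depth) && params$max_depth == 0) params$max_depth <- NULL
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  pl <- c(obj, params, list(nthread = 1, seed = as.integer(seed)))
  booster <- xgboost::xgb.train(params = do.call(xgboost::xgb.params, pl),
                                data = dm, nrounds = as.integer(n_rounds),
                                verbose = 0)
  booster
}

.xgb_predict <- function(booster, x, task) {
  p <- predict(booster, xgboost::xgb.DMatrix(x, nthread = 1))
  if (task$trait_type == "multiclass" && is.null(dim(p)))
    p <- matrix(p, nrow = nrow(x), byrow = TRUE)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# class predictions from probabilistic outputs
.pred_class <- function(p, task) {
  switch(task$trait_type,
    binary = as.integer(p >= 0.5),
    multiclass = max.col(p, "first") - 1L,
    stop("not a classification task"))
}

# encode labels to the numeric coding used by all families:
# classification -> integer codes 0..K-1 in class_labels order
.encode_labels <- function(y, task, class_labels = NULL) {
  if (task$trait_type == "regression") return(as.numeric(y))
  if (is.null(class_labels)) class_labels <- sort(unique(as.character(y)))
  code <- match(as.character(y), class_labels) - 1L
  if (anyNA(code)) stop("labels outside the declared class set")
  code
}

.score_fold <- function(pred, y, task) {
  if (task$trait_type == "regression") {
    sqrt(mean((pred - y)^2))  # fold RMSE, lower is better
  } else {
    100 * mean(.pred_class(pred, task) == y)  # fold accuracy
  }
}

.fit_family <- function(family, x, y, task, seed, xgb_params = list(),
                        nn_epochs = 200L, arch = NULL) {
  switch(family,
    XGB = .xgb_fit(x, y, task, xgb_params, seed),
    RF = {
      set.seed(as.integer(seed))
      yy <- if (task$trait_type == "regression") y else factor(y)
      randomForest::randomForest(x = x, y = yy,
                                 ntree = .arch_constants$RF$n_trees,
                                 mtry = max(1, floor(sqrt(ncol(x)))))
    },
    CNN = , DNN = {
      m <- build_model(arch %||% arch_spec(family), task, ncol(x))
      nn_fit(m$net, x, y, task$trait_type, epochs = nn_epochs,
             batch_size = batch_size_for(nrow(x)),
             lr = .arch_constants$optimizer$learning_rate, seed = seed)
    },
    stop("unknown family ", family))
}

.predict_family <- function(family, fitted, x, task) {
  switch(family,
    XGB = .xgb_predict(fitted, x, task),
    RF = {
      if (task$trait_type == "regression") as.numeric(predict(fitted, x))
      else if (task$trait_type == "binary")
        predict(fitted, x, type = "prob")[, 2]
      else predict(fitted, x, type = "prob")
    },
    CNN = , DNN = nn_predict(fitted, x))
}

# inner CV score of one hyperparameter configuration (higher is better)
.inner_cv_score <- function(x, y, task, params, k, seed) {
  folds <- make_folds(y, k, stratified = task$trait_type != "regression",
                      seed = seed)
  scores <- vapply(seq_len(k), function(fi) {
    tr <- folds != fi
    fit <- .xgb_fit(x[tr, , drop = FALSE], y[tr], task, params, seed)
    pred <- .xgb_predict(fit, x[!tr, , drop = FALSE], task)
    s <- .score_fold(pred, y[!tr], task)
    if (task$trait_type == "regression") -s else s
  }, numeric(1))
  mean(scores)
}

.sample_config <- function(space, u) {
  # u: numeric vector in [0,1]^d mapped through the (possibly log) bounds
  cfg <- list()
  nms <- names(space$bounds)
  for (i in seq_along(nms)) {
    b <- space$bounds[[i]]
    if (nms[i] %in% space$log_scale) {
      v <- 10^(log10(b[1]) + u[i] * (log10(b[2]) - log10(b[1])))
    } else {
      v <- b[1] + u[i] * (b[2] - b[1])
    }
    if (nms[i] %in% space$integer_params) v <- as.integer(round(v))
    cfg[[nms[i]]] <- v
  }
  cfg
}

#' Tune XGBoost hyperparameters by sequential model-based search
#'
#' Bayesian-style optimisation over the named search space: a Latin
#' hypercube seeds the design, then a random-forest surrogate fitted to the
#' evaluated (configuration, inner-CV score) pairs proposes each next
#' configuration by expected improvement over a random candidate pool.
#' Scores are mean inner-CV accuracy (classification) or negative RMSE
#' (regression). Deterministic under the space's seed.
#'
#' @param x,y training features and encoded labels (0..K-1 integer codes for
#'   classification, numeric for regression).
#' @param space a [tune_space()].
#' @param task a [task_spec()].
#' @param inner_k inner CV folds (default 3).
#' @return list with `best_params` (all inside their bounds), `best_score`,
#'   and the search `history` data.frame.
#' @export
tune_xgboost <- function(x, y, space, task, inner_k = 3L) {
  if (task$trait_type != "regression") {
    tab <- table(y)
    if (length(tab) < 2) stop("degenerate labels: only one class present")
    if (min(tab) < 2) stop("need at least 2 samples per class")
  }
  set.seed(space$seed)
  d <- length(space$bounds)
  n_iter <- space$n_search_iterations
  n_init <- min(max(5L, d %/% 2L), n_iter)
  design <- lhs::randomLHS(n_init, d)
  us <- lapply(seq_len(n_init), function(i) design[i, ])
  configs <- list(); scores <- numeric(0)
  eval_u <- function(u) {
    cfg <- .sample_config(space, u)
    sc <- .inner_cv_score(x, y, task, cfg, inner_k, space$seed)
    configs[[length(configs) + 1L]] <<- cfg
    scores[length(scores) + 1L] <<- sc
    u
  }
  umat <- matrix(NA_real_, 0, d)
  for (u in us) umat <- rbind(umat, eval_u(u))
  while (length(scores) < n_iter) {
    # random-forest surrogate with per-tree spread as the uncertainty proxy
    cand <- matrix(runif(500 * d), ncol = d)
    if (length(scores) >= 5 && length(unique(scores)) > 1) {
      sur <- suppressWarnings(
        randomForest::randomForest(x = umat, y = scores, ntree = 100))
      pa <- predict(sur, cand, predict.all = TRUE)
      mu <- pa$aggregate
      sdev <- apply(pa$individual, 1, sd)
      best <- max(scores)
      z <- (mu - best) / pmax(sdev, 1e-9)
      ei <- (mu - best) * pnorm(z) + sdev * dnorm(z)
      pick <- cand[which.max(ei), ]
    } else {
      pick <- cand[1, ]
    }
    umat <- rbind(umat, eval_u(pick))
  }
  best_i <- which.max(scores)
  history <- cbind(as.data.frame(do.call(rbind, lapply(configs, as.data.frame))),
                   score = scores)
  list(best_params = configs[[best_i]], best_score = scores[best_i],
       history = history)
}

#' Fit a single XGBoost model
#'
#' Direct single fit (no cross-validation) at the given hyperparameters,
#' used for interpretation experiments where one booster per dataset is
#' enough. Single-threaded and deterministic under the seed.
#'
#' @param x feature matrix; `y` labels encoded as 0..K-1 integer codes
#'   (classification) or numerics (regression).
#' @param y encoded labels/values.
#' @param task a [task_spec()].
#' @param params named XGBoost parameters (e.g. from [tune_xgboost()]);
#'   `n_estimators` sets the boosting rounds (default 100).
#' @param seed integer seed.
#' @return an xgboost booster.
#' @export
fit_xgboost <- function(x, y, task, params = list(), seed = 1L) {
  .xgb_fit(x, y, task, params, seed)
}

#' Cross-validation configuration
#'
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return list of class `cv_config`. Folds are stratified for
#'   classification tasks and unstratified for regression; the model kept
#'   is the best fold-validation performer (highest accuracy or lowest
#'   RMSE).
#' @export
cv_config <- function(k = 10L, seed = 1L) {
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "cv_config")
}

#' Assign cross-validation folds
#'
#' @param y labels (used for stratification) or any vector of length n.
#' @param k number of folds.
#' @param stratified stratify on `y`'s classes.
#' @param seed integer seed.
#' @return integer vector of fold ids 1..k, one per sample; every sample is
#'   in exactly one validation fold.
#' @export
make_folds <- function(y, k, stratified = FALSE, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(y)
  folds <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  folds
}

#' Cross-validate a model family and keep the best fold's model
#'
#' Trains one model per fold on the k-1 training folds and scores it on the
#' held-out fold (accuracy for classification, RMSE for regression). The
#' model with the best fold-validation score is returned and used as-is for
#' holdout prediction.
#'
#' @param family `"XGB"`, `"RF"`, `"CNN"` or `"DNN"`.
#' @param x training feature matrix (line ids as rownames).
#' @param y raw labels/values for the training lines.
#' @param task a [task_spec()].
#' @param cv a [cv_config()].
#' @param class_labels label order for classification coding.
#' @param xgb_params optional tuned XGBoost parameters.
#' @param nn_epochs training-epoch cap for the CNN/DNN families.
#' @return list of class `cv_fit`: `family`, `fitted`, `fold_scores`,
#'   `best_fold`, `task`, `train_ids`, `class_labels`.
#' @export
crossval_fit <- function(family, x, y, task, cv = cv_config(),
                         class_labels = NULL, xgb_params = list(),
                         nn_epochs = 200L) {
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < cv$k)
    stop("n_train = ", nrow(x), " is smaller than k = ", cv$k)
  stratified <- task$trait_type != "regression"
  if (stratified) {
    if (is.null(class_labels)) class_labels <- sort(unique(as.character(y)))
    tab <- table(factor(as.character(y), levels = class_labels))
    if (any(tab < cv$k))
      stop("class '", names(tab)[which.min(tab)], "' has ", min(tab),
           " member(s), fewer than k = ", cv$k, " under stratification")
  }
  y_enc <- .encode_labels(y, task, class_labels)
  folds <- make_folds(y_enc, cv$k, stratified = stratified, seed = cv$seed)
  fits <- vector("list", cv$k)
  fold_scores <- numeric(cv$k)
  for (fi in seq_len(cv$k)) {
    tr <- folds != fi
    fit <- .fit_family(family, x[tr, , drop = FALSE], y_enc[tr], task,
                       seed = cv$seed + fi, xgb_params = xgb_params,
                       nn_epochs = nn_epochs)
    pred <- .predict_family(family, fit, x[!tr, , drop = FALSE], task)
    fold_scores[fi] <- .score_fold(pred, y_enc[!tr], task)
    fits[[fi]] <- fit
  }
  best_fold <- if (task$trait_type == "regression")
    which.min(fold_scores) else which.max(fold_scores)
  structure(list(family = family, fitted = fits[[best_fold]],
                 fold_scores = fold_scores, best_fold = best_fold,
                 folds = folds, task = task,
                 train_ids = rownames(x), class_labels = class_labels),
            class = "cv_fit")
}

#' Accuracy as a percentage
#' @param pred,truth equal-length vectors of class labels/codes.
#' @return 100 x fraction correct.
#' @export
accuracy_percent <- function(pred, truth) {
  if (!length(truth)) stop("empty evaluation set")
  100 * mean(pred == truth)
}

#' RMSE as a percentage of the trait mean
#'
#' `100 * sqrt(mean((pred - truth)^2)) / reference_mean`. The reference
#' mean is the full-dataset trait mean, fixed per trait before splitting,
#' so the metric is comparable across models and datasets.
#'
#' @param pred,truth numeric vectors.
#' @param reference_mean the trait mean used as denominator; defaults to
#'   `mean(truth)`.
#' @return non-negative percentage.
#' @export
rmse_percent_of_mean <- function(pred, truth, reference_mean = mean(truth)) {
  if (!length(truth)) stop("empty evaluation set")
  if (abs(reference_mean) < .Machine$double.eps)
    stop("reference trait mean is zero; the metric is undefined")
  100 * sqrt(mean((pred - truth)^2)) / reference_mean
}

#' Evaluate a cross-validated model on the holdout set
#'
#' Guards against train/holdout leakage by line id, predicts with the best
#' fold's model, and computes classification accuracy (\%) or RMSE as a
#' percentage of the trait mean.
#'
#' @param fit a [crossval_fit()] result.
#' @param x_holdout holdout feature matrix (line ids as rownames, disjoint
#'   from the training ids).
#' @param y_holdout raw holdout labels/values.
#' @param reference_mean trait mean for the RMSE denominator (regression).
#' @return list of class `gs_metrics`: `metric_type`, `holdout_score`,
#'   `fold_scores`, `n_holdout`.
#' @export
evaluate <- function(fit, x_holdout, y_holdout, reference_mean = NULL) {
  stopifnot(inherits(fit, "cv_fit"))
  if (!nrow(x_holdout)) stop("empty holdout set")
  overlap <- intersect(rownames(x_holdout), fit$train_ids)
  if (length(overlap))
    stop("holdout lines overlap the training set: ",
         paste(head(overlap, 3), collapse = ", "))
  task <- fit$task
  pred <- .predict_family(fit$family, fit$fitted, x_holdout, task)
  if (task$trait_type == "regression") {
    if (is.null(reference_mean)) reference_mean <- mean(y_holdout)
    score <- rmse_percent_of_mean(pred, as.numeric(y_holdout), reference_mean)
    mt <- "rmse_pct_of_mean"
  } else {
    truth <- .encode_labels(y_holdout, task, fit$class_labels)
    score <- accuracy_percent(.pred_class(pred, task), truth)
    mt <- "accuracy_pct"
  }
  structure(list(metric_type = mt, holdout_score = score,
                 fold_scores = fit$fold_scores, n_holdout = nrow(x_holdout)),
            class = "gs_metrics")
}

#' Cross-model comparison summary
#'
#' From a tidy table of holdout metrics (one row per trait x family x
#' dataset), computes the average XGB-minus-DL and RF-minus-DL differences
#' (DL = unweighted mean of CNN and DNN per trait, then averaged over
#' traits; classification on accuracy, regression on error) and the
#' best-model tally per family (highest accuracy / lowest error per
#' trait x dataset; ties go to the earlier family in XGB, RF, CNN, DNN
#' order and are logged).
#'
#' @param metrics data.frame with columns `trait`, `family`, `metric_type`
#'   (`"accuracy_pct"` or `"rmse_pct_of_mean"`), `value`, and optionally
#'   `dataset` (defaults to a single dataset).
#' @return list of class `comparison_summary`: `differences` (data.frame),
#'   `tally` (named counts summing to the number of trait x dataset cells),
#'   `best_per_cell`, `n_cells`, `ties`.
#' @export
compare_models <- function(metrics) {
  req <- c("trait", "family", "metric_type", "value")
  if (!all(req %in% names(metrics))) stop("metrics needs columns: ",
                                          paste(req, collapse = ", "))
  if (!"dataset" %in% names(metrics)) metrics$dataset <- "full"
  fam_order <- intersect(c("XGB", "RF", "CNN", "DNN"), unique(metrics$family))
  has_dl <- all(c("CNN", "DNN") %in% fam_order)
  cells <- unique(metrics[, c("trait", "dataset")])
  for (i in seq_len(nrow(cells))) {
    sub <- metrics[metrics$trait == cells$trait[i] &
                   metrics$dataset == cells$dataset[i], ]
    if (!all(fam_order %in% sub$family))
      stop("missing family metric(s) for trait ", cells$trait[i],
           " dataset ", cells$dataset[i])
  }
  # per trait x dataset best family
  ties <- character(0)
  best <- vapply(seq_len(nrow(cells)), function(i) {
    sub <- metrics[metrics$trait == cells$trait[i] &
                   metrics$dataset == cells$dataset[i], ]
    sub <- sub[match(fam_order, sub$family), ]
    v <- sub$value
    best_v <- if (sub$metric_type[1] == "accuracy_pct") max(v) else min(v)
    hits <- which(abs(v - best_v) < 1e-12)
    if (length(hits) > 1)
      ties <<- c(ties, paste0(cells$trait[i], "/", cells$dataset[i]))
    fam_order[hits[1]]
  }, character(1))
  tally <- vapply(fam_order, function(f) sum(best == f), numeric(1))
  # family-minus-DL differences, per metric type (only when DL was run)
  diffs <- list()
  if (has_dl) for (mt in unique(metrics$metric_type)) {
    sub <- metrics[metrics$metric_type == mt, ]
    for (ds in unique(sub$dataset)) {
      s2 <- sub[sub$dataset == ds, ]
      per_trait <- split(s2, s2$trait)
      for (fam in c("XGB", "RF")) {
        d <- vapply(per_trait, function(tt) {
          dl <- mean(tt$value[tt$family %in% c("CNN", "DNN")])
          tt$value[tt$family == fam] - dl
        }, numeric(1))
        diffs[[length(diffs) + 1L]] <- data.frame(
          dataset = ds, metric_type = mt, comparison = paste0(fam, "-DL"),
          mean_difference = mean(d), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(differences = if (length(diffs)) do.call(rbind, diffs) else
                   data.frame(dataset = character(), metric_type = character(),
                              comparison = character(),
                              mean_difference = numeric()),
                 tally = tally,
                 best_per_cell = data.frame(cells, best_family = best,
                                            stringsAsFactors = FALSE),
                 n_cells = nrow(cells), ties = ties),
            class = "comparison_summary")
}

#' @export
#' @method print comparison_summary
print.comparison_summary <- function(x, ...) {
  cat("comparison over", x$n_cells, "trait x dataset cells\n")
  cat("best-model tally:", paste(names(x$tally), x$tally, sep = "=",
                                 collapse = ", "), "\n")
  print(x$differences, row.names = FALSE)
  invisible(x)
}
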