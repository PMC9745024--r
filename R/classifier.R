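#' Training configuration for the per-trisomy CNNs
#'
#' The default architecture is intentionally small — two convolution blocks
#' (ReLU + 2x2 max pooling) over a 4x8-average-pooled input, one dense
#' hidden layer and a sigmoid output — because a TRS image is a sparse
#' polyline whose informative feature is the vertical level of the target
#' segments, not fine texture. An optional random hyperparameter search is
#' available via [tune_models()].
#'
#' @param learning_rate Adam learning rate.
#' @param n_conv_layers number of conv blocks.
#' @param kernel_size odd kernel sizes, recycled across blocks.
#' @param n_conv_patches filters per block, recycled.
#' @param n_dense_layers number of dense hidden layers.
#' @param dense_units units per dense layer, recycled.
#' @param activation hidden activation (`"relu"` only).
#' @param dropout_rate dropout on dense hidden layers during training.
#' @param folds cross-validation folds (default 5).
#' @param cutoff positive-call probability cutoff (default 0.5, `>=`).
#' @param seed master seed fixing fold assignment, init, shuffling, dropout.
#' @param max_epochs training epoch budget per sub-model.
#' @param patience early-stopping patience on validation loss.
#' @param batch_size minibatch size.
#' @param class_weight weight positives by the negative/positive ratio
#'   (needed under the extreme imbalance typical of trisomy-13 cohorts).
#' @return a `TrainConfig` (list).
#' @export
train_config <- function(learning_rate = 1e-3, n_conv_layers = 2L,
                         kernel_size = 3L,
                         n_conv_patches = c(8L, 16L),
                         n_dense_layers = 1L, dense_units = 32L,
                         activation = "relu", dropout_rate = 0.3,
                         folds = 5L, cutoff = 0.5, seed = 1L,
                         max_epochs = 35L, patience = 5L,
                         batch_size = 32L, class_weight = TRUE) {
  stopifnot(folds >= 2, cutoff > 0, cutoff < 1,
            learning_rate > 0, n_conv_layers >= 1,
            all(kernel_size %% 2 == 1),
            dropout_rate >= 0, dropout_rate < 1,
            identical(activation, "relu"))
  structure(as.list(environment()), class = "TrainConfig")
}

#' Stratified cross-validation fold assignment
#'
#' Each class's indices are shuffled and dealt round-robin, so every fold
#' receives its share of the (possibly very few) positives.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id (1..k) per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(tabulate(fold[labels == 1], k) == 0))
    stop("a fold has zero positive samples: too few positives for ", k,
         "-fold stratified folding; reduce folds or enlarge the cohort")
  fold
}

# deterministic stratified train/validation split of the non-test samples;
# train:validation = 5:3 of the remaining 8/10 -> overall 5:3:2
.split_train_val <- function(idx, labels, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tr <- integer(0)
  for (cl in unique(labels[idx])) {
    ii <- sample(idx[labels[idx] == cl])
    ntr <- max(1, round(length(ii) * 5 / 8))
    tr <- c(tr, ii[seq_len(ntr)])
  }
  list(train = sort(tr), val = sort(setdiff(idx, tr)))
}

#' Train the per-trisomy model set
#'
#' For one target trisomy, trains one small CNN per cross-validation fold
#' and per FD representative (mean, median, IQR): samples are dealt into
#' `config$folds` stratified folds; for each fold the held-out fold is the
#' test split and the remainder is split 5:3 into training and validation
#' (5:3:2 overall); each sub-model is selected at its best validation loss.
#' Held-out (out-of-fold) probabilities are collected for every sample, and
#' the per-fold ensemble (median of the three representatives) is averaged
#' where folds overlap — for out-of-fold predictions each sample belongs to
#' exactly one test fold.
#'
#' @param images named list with elements `mean`, `median`, `iqr`, each a
#'   list of 200 x 400 image matrices in sample order.
#' @param labels binary 0/1 vector (1 = target trisomy).
#' @param config a `TrainConfig`.
#' @return `TrisomyModel`: per-representative per-fold networks, fold map,
#'   config, and `oof` (`data.table` of held-out probabilities: one row per
#'   sample with `p_mean`, `p_median`, `p_iqr`, `p_ensemble`).
#' @export
train_models <- function(images, labels, config = train_config()) {
  stopifnot(inherits(config, "TrainConfig"),
            all(c("mean", "median", "iqr") %in% names(images)))
  labels <- as.integer(labels)
  n <- length(labels)
  for (rp in c("mean", "median", "iqr"))
    if (length(images[[rp]]) != n)
      stop("images and labels disagree in length for representative ", rp)
  fold <- stratified_folds(labels, config$folds, config$seed)
  stacks <- lapply(images[c("mean", "median", "iqr")],
                   function(l) .prep_stack(.stack_images(l)))
  nets <- list()
  oof_rep <- matrix(NA_real_, n, 3,
                    dimnames = list(NULL, c("mean", "median", "iqr")))
  for (ri in 1:3) {
    rp <- c("mean", "median", "iqr")[ri]
    X <- stacks[[rp]]
    nets[[rp]] <- vector("list", config$folds)
    for (f in seq_len(config$folds)) {
      test_idx <- which(fold == f)
      rest <- which(fold != f)
      sp <- .split_train_val(rest, labels, config$seed + 31L * f)
      cfg <- config
      cfg$seed <- config$seed + 1000L * f + 100000L * ri
      net <- .cnn_train(X[, , , sp$train, drop = FALSE], labels[sp$train],
                        X[, , , sp$val, drop = FALSE], labels[sp$val], cfg)
      nets[[rp]][[f]] <- net
      oof_rep[test_idx, rp] <- .cnn_predict(net, X[, , , test_idx,
                                                   drop = FALSE])
    }
  }
  oof <- data.table(
    p_mean = oof_rep[, "mean"], p_median = oof_rep[, "median"],
    p_iqr = oof_rep[, "iqr"],
    p_ensemble = ensemble_median(oof_rep[, "mean"], oof_rep[, "median"],
                                 oof_rep[, "iqr"]),
    fold = fold, label = labels)
  structure(list(nets = nets, fold = fold, config = config, oof = oof),
            class = "TrisomyModel")
}

#' Predict per-representative probabilities for new samples
#'
#' Each representative's probability is the mean over the fold sub-models'
#' outputs; the ensemble is the per-fold median of the three
#' representatives, averaged over folds.
#'
#' @param model a `TrisomyModel`.
#' @param images named list (`mean`, `median`, `iqr`) of 200 x 400 image
#'   matrices, parallel across representatives.
#' @return `data.table` with `p_mean`, `p_median`, `p_iqr`, `p_ensemble`.
#' @export
predict_proba <- function(model, images) {
  stopifnot(inherits(model, "TrisomyModel"))
  stacks <- lapply(images[c("mean", "median", "iqr")],
                   function(l) .prep_stack(.stack_images(l)))
  n <- dim(stacks$mean)[4]
  k <- model$config$folds
  pf <- array(NA_real_, c(n, 3, k),
              dimnames = list(NULL, c("mean", "median", "iqr"), NULL))
  for (rp in c("mean", "median", "iqr"))
    for (f in seq_len(k))
      pf[, rp, f] <- .cnn_predict(model$nets[[rp]][[f]], stacks[[rp]])
  p_rep <- apply(pf, c(1, 2), mean)
  ens_fold <- apply(pf, c(1, 3), stats::median)  # median of reps, per fold
  data.table(p_mean = p_rep[, "mean"], p_median = p_rep[, "median"],
             p_iqr = p_rep[, "iqr"], p_ensemble = rowMeans(ens_fold))
}

#' Median-of-three ensemble probability
#'
#' The ensemble combines the mean-, median- and IQR-model probabilities by
#' their median (the middle order statistic), elementwise over samples or
#' folds. It always lies between the smallest and largest of the three.
#'
#' @param p_mean,p_median,p_iqr probabilities in \[0, 1\] (vectors of equal
#'   length).
#' @return numeric vector of ensemble probabilities.
#' @export
ensemble_median <- function(p_mean, p_median, p_iqr) {
  m <- cbind(p_mean, p_median, p_iqr)
  apply(m, 1, stats::median)
}

#' Binary call from a probability
#'
#' @param probability probability in \[0, 1\].
#' @param cutoff call threshold; positive iff `probability >= cutoff`
#'   (default 0.5).
#' @return logical vector.
#' @export
call_sample <- function(probability, cutoff = 0.5) {
  stopifnot(all(probability >= 0 & probability <= 1))
  probability >= cutoff
}

#' Save / load a trained model bundle
#'
#' The bundle directory holds the serialized fold networks, the fold map
#' and the training configuration as JSON, and reloads to bit-identical
#' predictions.
#'
#' @param model a `TrisomyModel`.
#' @param dir bundle directory (created if absent).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$nets, file.path(dir, "nets.rds"))
  saveRDS(model$oof, file.path(dir, "oof.rds"))
  cfg <- model$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "")],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(data.table(sample = seq_along(model$fold),
                                fold = model$fold),
                     file.path(dir, "folds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(train_config, cfgl[names(cfgl) %in%
                                      names(formals(train_config))])
  folds <- utils::read.table(file.path(dir, "folds.tsv"), header = TRUE,
                             sep = "\t")
  structure(list(nets = readRDS(file.path(dir, "nets.rds")),
                 fold = folds$fold, config = cfg,
                 oof = readRDS(file.path(dir, "oof.rds"))),
            class = "TrisomyModel")
}

#' Small random hyperparameter search
#'
#' Draws `budget` configurations from documented ranges, trains each with
#' the same folds, and returns the one with the lowest mean validation
#' loss. A desk-scale stand-in for large Bayesian searches.
#'
#' @param images,labels as in [train_models()].
#' @param budget number of configurations tried.
#' @param base a `TrainConfig` supplying everything not searched.
#' @return list with `best_config`, `results` table and the retrained
#'   `model` under the best configuration.
#' @export
tune_models <- function(images, labels, budget = 4L,
                        base = train_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(base$seed)
  grid <- data.table(
    learning_rate = 10^stats::runif(budget, -3.5, -2.5),
    n_conv_patches1 = sample(c(4L, 8L, 16L), budget, replace = TRUE),
    dropout_rate = stats::runif(budget, 0.1, 0.5))
  res <- numeric(budget)
  models <- vector("list", budget)
  for (i in seq_len(budget)) {
    cfg <- base
    cfg$learning_rate <- grid$learning_rate[i]
    cfg$n_conv_patches <- c(grid$n_conv_patches1[i],
                            2L * grid$n_conv_patches1[i])
    cfg$dropout_rate <- grid$dropout_rate[i]
    models[[i]] <- train_models(images, labels, cfg)
    res[i] <- mean(vapply(unlist(models[[i]]$nets, recursive = FALSE),
                          function(nt) nt$val_loss, numeric(1)))
  }
  best <- which.min(res)
  list(best_config = models[[best]]$config,
       results = cbind(grid, val_loss = res), model = models[[best]])
}
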