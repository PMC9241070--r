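# Stratified (optionally grouped) k-fold assignment and the rotating
# train/validation/test cross-validation harness.

#' Stratified k-fold assignment
#'
#' Folds are stratified by label so each fold's class ratio matches the
#' dataset within one site per class.  When `groups` are given (e.g. cluster
#' ids of equivalent sites), a group is never split across folds.
#'
#' @param labels Character/factor labels per site.
#' @param k Number of folds (default 10; must be at least 3 so the
#'   train/validation/test rotation is possible).
#' @param groups Optional group ids per site.
#' @param seed Optional integer seed.
#' @return Integer vector of fold indices (1..k) per site, class
#'   `fold_split`.
#' @export
make_folds <- function(labels, k = 10, groups = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(k >= 3)
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(groups)) groups <- seq_len(n)
  groups <- as.character(groups)
  if (k > length(unique(groups)))
    stop("k = ", k, " exceeds the number of groups (",
         length(unique(groups)), ")")
  fold_of_group <- setNames(rep(NA_integer_, length(unique(groups))),
                            unique(groups))
  fold_total <- integer(k)
  for (cl in unique(labels)) {
    gs <- unique(groups[labels == cl])
    gs <- gs[is.na(fold_of_group[gs])]    # groups spanning classes keep
    gs <- sample(gs)                      # their first assignment
    cl_count <- integer(k)
    for (g in gs) {
      sz <- sum(groups == g)
      # fill the fold with the fewest sites of this class, then smallest
      target <- order(cl_count, fold_total)[1]
      fold_of_group[g] <- target
      cl_count[target] <- cl_count[target] + sz
      fold_total[target] <- fold_total[target] + sz
    }
  }
  out <- unname(fold_of_group[groups])
  structure(out, k = k, class = "fold_split")
}

#' Cross-validate the site classifier
#'
#' The rotating holdout protocol: the dataset is split into `k` folds; in
#' rotation t, fold t is the held-out test set, fold `t %% k + 1` the
#' validation set for early stopping, and the remaining k-2 folds the
#' training set.  Every site is therefore predicted exactly once as test
#' data.
#'
#' @param x Labelled `site_dataset` (or list of matrices with `y`).
#' @param y Labels when `x` is a plain list.
#' @param k Number of folds (default 10).
#' @param config,control See [mbs_net_config()], [mbs_train_control()].
#' @param groups Optional group ids (kept intact across folds).
#' @param seed Optional integer seed for fold assignment and training.
#' @return Object of class `mbsnet_cv`: per-fold models and test
#'   predictions, pooled predictions, per-fold and aggregate accuracy.
#' @export
mbsnet_cv <- function(x, y = NULL, k = 10, config = mbs_net_config(),
                      control = mbs_train_control(), groups = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- .as_matrix_list(x)
  lab <- .labels_of(x, y)
  ids <- .site_ids_of(x, length(X))
  folds <- make_folds(lab, k = k, groups = groups)
  models <- vector("list", k)
  preds <- vector("list", k)
  for (t in seq_len(k)) {
    val_fold <- t %% k + 1L
    i_test <- which(folds == t)
    i_val <- which(folds == val_fold)
    i_tr <- which(folds != t & folds != val_fold)
    fit <- mbsnet(X[i_tr], lab[i_tr],
                  validation = X[i_val], validation_y = lab[i_val],
                  config = config, control = control)
    p <- predict(fit, X[i_test])
    p$site_id <- ids[i_test]
    p$label <- lab[i_test]
    p$fold <- t
    models[[t]] <- fit
    preds[[t]] <- p
  }
  pooled <- do.call(rbind, preds)
  acc <- vapply(preds, function(p) mean(p$class == p$label), numeric(1))
  cm <- confusion_matrix(pooled, pooled$label,
                         threshold = control$threshold)
  structure(list(k = k, folds = folds, models = models,
                 predictions = pooled,
                 fold_accuracy = acc,
                 mean_accuracy = mean(acc), sd_accuracy = sd(acc),
                 confusion = cm,
                 labels = lab, site_ids = ids,
                 config = config, control = control),
            class = "mbsnet_cv")
}

#' @export
print.mbsnet_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d sites\n",
              x$k, length(x$labels)))
  cat(sprintf("  mean test accuracy: %.3f +/- %.3f\n",
              x$mean_accuracy, x$sd_accuracy))
  print(x$confusion)
  invisible(x)
}

#' @export
summary.mbsnet_cv <- function(object, ...) {
  print(object)
  ms <- metric_set(object$confusion)
  print(ms)
  roc <- roc_curve(object$predictions$p_physiological,
                   object$predictions$label)
  cat(sprintf("  pooled AUC: %.3f\n", roc$auc))
  invisible(list(metrics = ms, auc = roc$auc))
}
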