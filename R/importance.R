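# Perturbation-based feature importance: degrade one feature (or group of
# columns) with Gaussian noise scaled by the feature's empirical domain
# magnitude and measure the drop in test accuracy.

#' Default feature grouping for importance reports
#'
#' The 20 amino-acid frequency columns individually, absolute and relative
#' accessibility individually, the three binding-role columns as one group,
#' and the four secondary-structure columns as one group: 24 groups.
#'
#' @return Named list of 1-based column-index vectors.
#' @export
default_feature_groups <- function() {
  g <- c(as.list(setNames(.COL_FREQ, .AA)),
         list(abs_sasa = .COL_ABS, rel_sasa = .COL_REL,
              role = .COL_ROLE, sec_struct = .COL_SS))
  g
}

#' Empirical magnitude of a feature's domain
#'
#' `max - min` of the feature over all residues of all sites in the
#' reference (training) data.
#'
#' @param x Dataset (`site_dataset` or list of matrices).
#' @param feature_index Column index (1-based).
#' @return Scalar magnitude (with a warning when the feature is constant).
#' @export
feature_magnitude <- function(x, feature_index) {
  X <- .as_matrix_list(x)
  if (length(X) == 0) stop("empty dataset")
  vals <- unlist(lapply(X, function(m) range(m[, feature_index])))
  a <- max(vals) - min(vals)
  if (a == 0) warning("feature ", feature_index,
                      " is constant; magnitude 0")
  a
}

#' Perturb feature columns with scaled Gaussian noise
#'
#' Each listed column receives independent per-residue N(0, 1) draws scaled
#' by that column's magnitude `alpha`; all other columns are unchanged.
#' Values are not clipped to their valid ranges (the perturbation is purely
#' additive).
#'
#' @param x Dataset (`site_dataset` or list of matrices).
#' @param columns Column indices to perturb.
#' @param alpha Magnitudes, recycled over `columns`.
#' @param seed Optional integer seed.
#' @return Object of the same form as `x` with perturbed matrices.
#' @export
perturb_features <- function(x, columns, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(columns) >= 1, all(alpha >= 0))
  alpha <- rep_len(alpha, length(columns))
  X <- .as_matrix_list(x)
  Xp <- lapply(X, function(m) {
    for (k in seq_along(columns))
      m[, columns[k]] <- m[, columns[k]] + alpha[k] * rnorm(nrow(m))
    m
  })
  if (inherits(x, "site_dataset")) {
    out <- x
    for (i in seq_along(Xp)) out$sites[[i]]$values <- Xp[[i]]
    out
  } else Xp
}

#' Importance of feature groups for one model and test set
#'
#' `I = Acc(baseline) - Acc(perturbed)`, both accuracies computed on the
#' same test set at the same threshold.
#'
#' @param model A fitted `mbsnet`.
#' @param x Test set (dataset or list of matrices).
#' @param y Test labels (`NULL` when `x` is labelled).
#' @param groups Named list of column groups (default
#'   [default_feature_groups()]).
#' @param reference Data used to compute the magnitudes (default: the test
#'   set itself; pass the training set for the standard protocol).
#' @param threshold Decision threshold (default: the model's).
#' @param seed Optional integer seed for the noise draws.
#' @return Data frame with `group`, `importance`, `baseline_accuracy`,
#'   `perturbed_accuracy`.
#' @export
feature_importance <- function(model, x, y = NULL,
                               groups = default_feature_groups(),
                               reference = x, threshold = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(threshold)) threshold <- model$control$threshold
  X <- .as_matrix_list(x)
  if (length(X) == 0) stop("empty test set")
  lab <- .labels_of(x, y)
  alphas <- vapply(seq_len(ncol(X[[1]])), function(j)
    suppressWarnings(feature_magnitude(reference, j)), numeric(1))
  acc_of <- function(Xs) {
    p <- predict(model, Xs, threshold = threshold)
    mean(p$class == lab)
  }
  base <- acc_of(X)
  rows <- lapply(names(groups), function(g) {
    cols <- groups[[g]]
    Xp <- perturb_features(X, cols, alphas[cols])
    pa <- acc_of(Xp)
    data.frame(group = g, importance = base - pa,
               baseline_accuracy = base, perturbed_accuracy = pa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fold-wise importance over a cross-validation run
#'
#' For each rotation, recomputes the magnitudes on that rotation's training
#' folds, perturbs that rotation's test fold, and evaluates the accuracy
#' drop with that rotation's model; reports mean and standard deviation of
#' `I` per group over the folds.
#'
#' @param cv An `mbsnet_cv` object.
#' @param x The dataset the cross-validation was run on.
#' @param y Labels when `x` is a plain list.
#' @param groups Named list of column groups.
#' @param seed Optional integer seed.
#' @return Object of class `mbs_importance`: `table` (group, mean, sd),
#'   `fold_values` (group x fold matrix), `baseline` (per-fold accuracy).
#' @export
importance_over_folds <- function(cv, x, y = NULL,
                                  groups = default_feature_groups(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- .as_matrix_list(x)
  lab <- .labels_of(x, y)
  k <- cv$k
  fold_vals <- matrix(NA_real_, length(groups), k,
                      dimnames = list(names(groups), NULL))
  baseline <- numeric(k)
  for (t in seq_len(k)) {
    val_fold <- t %% k + 1L
    i_test <- which(cv$folds == t)
    i_tr <- which(cv$folds != t & cv$folds != val_fold)
    imp <- feature_importance(cv$models[[t]], X[i_test], lab[i_test],
                              groups = groups, reference = X[i_tr])
    fold_vals[, t] <- imp$importance
    baseline[t] <- imp$baseline_accuracy[1]
  }
  tab <- data.frame(group = names(groups),
                    mean = rowMeans(fold_vals),
                    sd = apply(fold_vals, 1, sd),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean), ]
  structure(list(table = tab, fold_values = fold_vals,
                 baseline = baseline), class = "mbs_importance")
}

#' @export
print.mbs_importance <- function(x, ...) {
  cat("Perturbation importance (mean +/- sd over",
      ncol(x$fold_values), "folds)\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.mbs_importance <- function(x, ...) {
  tab <- x$table
  graphics::barplot(rev(tab$mean), names.arg = rev(tab$group),
                    horiz = TRUE, las = 1, xlab = "importance I",
                    cex.names = 0.7, ...)
  invisible(x)
}

#' Write an importance report TSV
#'
#' @param x An `mbs_importance`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(x, path) {
  out <- cbind(x$table,
               as.data.frame(x$fold_values[x$table$group, , drop = FALSE]))
  names(out)[-(1:3)] <- paste0("fold_", seq_len(ncol(x$fold_values)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
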