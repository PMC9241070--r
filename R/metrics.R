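# Evaluation: confusion matrices, the derived metric suite, ROC/AUC by
# explicit threshold sweep, and confidence-binned error rates.  The positive
# class is "physiological" throughout.

.p_phys_of <- function(predictions) {
  if (is.data.frame(predictions)) {
    if (!"p_physiological" %in% names(predictions))
      stop("prediction frame lacks a p_physiological column")
    predictions$p_physiological
  } else as.numeric(predictions)
}

.align_predictions <- function(predictions, labels) {
  p <- .p_phys_of(predictions)
  if (is.data.frame(predictions) && "site_id" %in% names(predictions) &&
      !is.null(names(labels))) {
    missing <- setdiff(predictions$site_id, names(labels))
    if (length(missing) > 0)
      stop("no label for site(s): ", paste(missing, collapse = ", "))
    labels <- labels[predictions$site_id]
  }
  if (length(p) != length(labels))
    stop("predictions and labels differ in length")
  list(p = p, y = as.character(labels))
}

#' Confusion matrix at a threshold
#'
#' A site is called physiological iff its physiological probability is
#' strictly greater than `threshold`.
#'
#' @param predictions Numeric vector of physiological probabilities, or a
#'   prediction frame from [predict.mbsnet()] (aligned by `site_id` when
#'   `labels` is named).
#' @param labels True labels.
#' @param threshold Decision threshold beta (default 0.5).
#' @return Object of class `mbs_confusion` with `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_matrix <- function(predictions, labels, threshold = 0.5) {
  al <- .align_predictions(predictions, labels)
  pos_call <- al$p > threshold
  pos <- al$y == "physiological"
  structure(list(TP = sum(pos_call & pos), FN = sum(!pos_call & pos),
                 FP = sum(pos_call & !pos), TN = sum(!pos_call & !pos),
                 threshold = threshold),
            class = "mbs_confusion")
}

#' @export
print.mbs_confusion <- function(x, ...) {
  cat(sprintf("  confusion (beta = %.2f): TP %d  FN %d  FP %d  TN %d\n",
              x$threshold, x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Metric suite from a confusion matrix
#'
#' PPV, TPR (recall), NPV, TNR (specificity), FDR = 1 - PPV, ACC, and MCC.
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' as 0.
#'
#' @param cm An `mbs_confusion`, or a vector/list with TP, FN, FP, TN.
#' @return Object of class `mbs_metric_set`.
#' @export
metric_set <- function(cm) {
  cm <- as.list(cm)
  TP <- as.numeric(cm$TP); FN <- as.numeric(cm$FN)
  FP <- as.numeric(cm$FP); TN <- as.numeric(cm$TN)
  total <- TP + FN + FP + TN
  if (total == 0) stop("empty confusion matrix")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  ppv <- safe(TP, TP + FP)
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  structure(list(
    PPV = ppv,
    TPR = safe(TP, TP + FN),
    NPV = safe(TN, TN + FN),
    TNR = safe(TN, TN + FP),
    FDR = if (is.na(ppv)) NA_real_ else 1 - ppv,
    ACC = (TP + TN) / total,
    MCC = if (mcc_den > 0) (TP * TN - FP * FN) / mcc_den else NA_real_),
    class = "mbs_metric_set")
}

#' @export
print.mbs_metric_set <- function(x, ...) {
  v <- unlist(x)
  cat("  ", paste(sprintf("%s %.3f", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' The set of (1 - TNR(beta), TPR(beta)) pairs obtained by sweeping the
#' threshold beta over the unique scores (ties grouped), augmented with the
#' (0,0) and (1,1) endpoints; AUC by the trapezoidal rule.
#'
#' @param scores Physiological probabilities (or any monotone score).
#' @param labels True labels (both classes must be present).
#' @return Object of class `mbs_roc`: `points` (data frame with
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  scores <- .p_phys_of(scores)
  y <- as.character(labels) == "physiological"
  if (!any(y) || all(y)) stop("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- !duplicated(s)                    # ties grouped at one threshold
  tp <- cumsum(yy); fp <- cumsum(!yy)
  last <- c(which(grp[-1]) , length(s))    # last index of each tie group
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = c(Inf, s[last]),
                                     fpr = fpr, tpr = tpr),
                 auc = auc), class = "mbs_roc")
}

#' @export
print.mbs_roc <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds, AUC = %.3f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.mbs_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "1 - TNR", ylab = "TPR", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Confidence-binned prediction counts and error rates
#'
#' Bins the confidence (absolute difference of the two class probabilities)
#' into intervals of `width` over [0, 1] — the final bin is closed at 1 —
#' and reports the count and error rate per bin, plus the aggregate count
#' and error rate for predictions with confidence strictly above
#' `high_cutoff`.
#'
#' @param predictions Prediction frame from [predict.mbsnet()] (needs
#'   `confidence` and `class`), or a numeric confidence vector with
#'   `correct` supplied.
#' @param labels True labels (when `predictions` is a frame).
#' @param correct Logical vector of prediction correctness (alternative to
#'   `labels`).
#' @param width Bin width (default 0.1; must divide 1).
#' @param high_cutoff Aggregate-confidence cutoff (default 0.85).
#' @return Object of class `mbs_confidence_bins`: `bins` data frame
#'   (`lower`, `upper`, `count`, `error_rate` — `NA` for empty bins),
#'   `high_count`, `high_error_rate`, `n`.
#' @export
confidence_bins <- function(predictions, labels = NULL, correct = NULL,
                            width = 0.1, high_cutoff = 0.85) {
  nb <- round(1 / width)
  if (abs(nb * width - 1) > 1e-9) stop("width must divide 1 evenly")
  if (is.data.frame(predictions)) {
    conf <- predictions$confidence
    if (is.null(correct)) {
      if (is.null(labels)) stop("labels (or correct) required")
      correct <- predictions$class == as.character(labels)
    }
  } else {
    conf <- as.numeric(predictions)
    if (is.null(correct)) stop("correct required with a confidence vector")
  }
  idx <- pmin(floor(conf / width) + 1L, nb)   # final bin closed at 1
  count <- tabulate(idx, nbins = nb)
  err <- vapply(seq_len(nb), function(b)
    if (count[b] > 0) mean(!correct[idx == b]) else NA_real_, numeric(1))
  high <- conf > high_cutoff
  structure(list(
    bins = data.frame(lower = width * (seq_len(nb) - 1),
                      upper = width * seq_len(nb),
                      count = count, error_rate = err),
    high_cutoff = high_cutoff,
    high_count = sum(high),
    high_error_rate = if (any(high)) mean(!correct[high]) else NA_real_,
    n = length(conf)), class = "mbs_confidence_bins")
}

#' @export
print.mbs_confidence_bins <- function(x, ...) {
  cat("Confidence bins (n =", x$n, ")\n")
  print(x$bins, row.names = FALSE)
  cat(sprintf("  confidence > %.2f: %d predictions, error rate %.3f\n",
              x$high_cutoff, x$high_count, x$high_error_rate))
  invisible(x)
}
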