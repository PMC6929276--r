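# Confusion-matrix metrics, ROC/AUC, and point-biserial feature ranking.

#' Confusion counts
#'
#' @param labels,predictions equal-length binary (0/1) vectors.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN` (summing to n).
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop_usage("labels and predictions have different lengths")
  }
  if (!all(c(labels, predictions) %in% c(0, 1))) {
    stop_usage("labels and predictions must be binary 0/1")
  }
  c(TP = sum(labels == 1 & predictions == 1),
    FP = sum(labels == 0 & predictions == 1),
    TN = sum(labels == 0 & predictions == 0),
    FN = sum(labels == 1 & predictions == 0))
}

#' Precision, recall and F1
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2*precision*recall/(precision+recall)`. Undefined denominators are
#' an explicit error, never a silent zero.
#'
#' @param counts output of [confusion_counts()].
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (tp + fp == 0) stop_usage("precision undefined: no predicted positives")
  if (tp + fn == 0) stop_usage("recall undefined: no true positives in labels")
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Classification accuracy
#'
#' @param counts output of [confusion_counts()]; total must be positive.
#' @return `(TP + TN) / n`.
#' @export
classification_accuracy <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop_usage("accuracy undefined on zero samples")
  (counts[["TP"]] + counts[["TN"]]) / n
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney statistic — the probability that a random
#' positive scores above a random negative, ties counting one half — which
#' equals the trapezoidal area under the ROC curve. ROC points are emitted
#' at every distinct score threshold.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels binary labels; both classes must be present.
#' @return List with `roc` (`data.frame` of `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_usage("length mismatch")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop_usage("ROC requires both classes present")
  }
  r <- rank(scores)                     # midranks handle ties
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie block
  tpr <- cumsum(y == 1)[last] / npos
  fpr <- cumsum(y == 0)[last] / nneg
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, s[last]))
  list(roc = roc, auc = auc)
}

#' Evaluation report
#'
#' Bundles confusion counts, precision/recall/F1, accuracy and (when scores
#' are given) ROC/AUC. A metric whose denominator is undefined on this data
#' (e.g. precision with no predicted positives) is stored as `NULL` with an
#' explanatory `notes` entry rather than aborting the whole report.
#'
#' @param labels binary truth.
#' @param predictions binary predictions.
#' @param scores optional continuous scores for ROC/AUC.
#' @return Object of class `eval_report`.
#' @export
eval_report <- function(labels, predictions, scores = NULL) {
  counts <- confusion_counts(labels, predictions)
  notes <- character()
  prf <- tryCatch(as.list(precision_recall_f1(counts)),
                  error = function(e) {
                    notes <<- c(notes, conditionMessage(e))
                    list(precision = NULL, recall = NULL, f1 = NULL)
                  })
  out <- c(list(counts = counts), prf,
           list(accuracy = classification_accuracy(counts)))
  if (!is.null(scores)) {
    ra <- tryCatch(roc_auc(scores, labels), error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      NULL
    })
    out$auc <- ra$auc
    out$roc <- ra$roc
  }
  out$notes <- notes
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf(
    "eval_report: n=%d  precision=%s recall=%s F1=%s accuracy=%s%s\n",
    sum(x$counts), fmt(x$precision), fmt(x$recall), fmt(x$f1),
    fmt(x$accuracy),
    if (!is.null(x$auc)) sprintf(" AUC=%s", fmt(x$auc)) else ""))
  invisible(x)
}

#' Rank features by point-biserial Pearson correlation
#'
#' Computes the Pearson correlation between each feature column and the 0/1
#' label vector and ranks by descending absolute correlation. Constant
#' columns (correlation undefined) are excluded from the ranking and listed
#' separately.
#'
#' @param fm a [feature_matrix()].
#' @return Object of class `feature_ranking`: `data.frame` with `feature`,
#'   `r`, `rank`; constant columns in attribute `excluded`.
#' @export
pearson_rank <- function(fm) {
  y <- fm$labels
  if (length(unique(y)) < 2L) {
    stop_data("labels are single-class; correlation with the label undefined")
  }
  sds <- apply(fm$features, 2, sd)
  usable <- is.finite(sds) & sds > 0
  if (!any(usable)) stop_data("all feature columns are constant")
  r <- as.vector(cor(fm$features[, usable, drop = FALSE], y))
  out <- data.frame(feature = colnames(fm$features)[usable], r = r)
  out <- out[order(-abs(out$r)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- colnames(fm$features)[!usable]
  class(out) <- c("feature_ranking", "data.frame")
  out
}
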