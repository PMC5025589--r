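#' Confusion counts from truth and prediction vectors
#'
#' @param truth,predicted Logical vectors of the same length (TRUE =
#'   tail-anchored).
#' @return List with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(tp = sum(truth & predicted), fp = sum(!truth & predicted),
       fn = sum(truth & !predicted), tn = sum(!truth & !predicted))
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FP+FN+TN); Sensitivity = TP/(TP+FN); Specificity =
#' TN/(FP+TN); BER = (FN/(TP+FN) + FP/(FP+TN)) / 2. Errors when either class
#' is empty (undefined ratios).
#'
#' @param tp,fp,fn,tn Non-negative counts. `tp` may also be a list with
#'   elements `tp`, `fp`, `fn`, `tn` (as from [confusion_counts()]).
#' @return One-row data frame: `accuracy`, `sensitivity`, `specificity`,
#'   `ber`.
#' @export
classification_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.list(tp)) {
    fp <- tp$fp; fn <- tp$fn; tn <- tp$tn; tp <- tp$tp
  }
  if (tp + fn == 0 || fp + tn == 0)
    stop_validation("metrics undefined: an empty positive or negative class")
  data.frame(accuracy = (tp + tn) / (tp + fp + fn + tn),
             sensitivity = tp / (tp + fn),
             specificity = tn / (fp + tn),
             ber = (fn / (tp + fn) + fp / (fp + tn)) / 2)
}

#' ROC curve and rank-based AUC
#'
#' The AUC equals the Mann-Whitney probability P(score_pos > score_neg) +
#' 0.5 P(equal), computed from midranks, and is therefore invariant under
#' any strictly increasing transform of the scores. Curve points are
#' (1 - specificity, sensitivity) at every distinct threshold (score >=
#' threshold is positive), from (0, 0) to (1, 1); the trapezoidal area under
#' this stepwise curve equals the rank-based AUC.
#'
#' @param scores_pos,scores_neg Numeric score vectors.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0L || nn == 0L)
    stop_validation("both score sets must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  th <- c(Inf, sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE))
  pts <- data.frame(threshold = th,
                    fpr = vapply(th, function(t) sum(scores_neg >= t) / nn, 0),
                    tpr = vapply(th, function(t) sum(scores_pos >= t) / np, 0))
  list(points = pts, auc = auc)
}

#' Per-negative-set evaluation report
#'
#' Summarises predictions against truth for each negative class separately
#' (TA vs SP, TA vs MP, TA vs NO) plus a pooled "Total" row, mirroring the
#' per-dataset contingency layout. Metrics are reported to 3 decimal places
#' (round-half-even).
#'
#' @param classes Character vector of true classes (`"TA"`, `"SP"`, `"MP"`,
#'   `"NO"`).
#' @param predicted Logical vector of predictions (TRUE = called TA).
#' @return Data frame with one row per negative set and a `Total` row:
#'   `negative_set`, `sensitivity`, `specificity`, `tp`, `fp`, `fn`, `tn`.
#' @export
evaluation_report <- function(classes, predicted) {
  stopifnot(length(classes) == length(predicted))
  pos <- classes == "TA"
  neg_sets <- intersect(c("SP", "MP", "NO"), unique(classes))
  one_row <- function(name, keep) {
    cc <- confusion_counts(pos[keep], predicted[keep])
    m <- classification_metrics(cc)
    data.frame(negative_set = name,
               sensitivity = round(m$sensitivity, 3L),
               specificity = round(m$specificity, 3L),
               tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(neg_sets, function(ns) one_row(ns, pos | classes == ns))
  rows <- c(rows, list(one_row("Total", rep(TRUE, length(classes)))))
  do.call(rbind, rows)
}
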