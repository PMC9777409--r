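# Binary diagnostic metrics from the confusion matrix, with the malignant
# class as positive by default, plus a threshold-sweep ROC curve with
# trapezoidal AUC.

#' Confusion counts for binary labels
#'
#' @param true_labels,predicted_labels equal-length vectors of class labels.
#' @param positive_class label treated as positive (default `"malignant"`).
#' @return object of class `confusion_counts`: list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(true_labels, predicted_labels, positive_class = "malignant") {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  tp <- sum(true_labels == positive_class & predicted_labels == positive_class)
  fp <- sum(true_labels != positive_class & predicted_labels == positive_class)
  tn <- sum(true_labels != positive_class & predicted_labels != positive_class)
  fn <- sum(true_labels == positive_class & predicted_labels != positive_class)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn), class = "confusion_counts")
}

#' Scalar metrics from confusion counts
#'
#' precision = TP/(TP+FP); accuracy = (TP+TN)/N; recall = TP/(TP+FN);
#' F1 = 2PR/(P+R). A zero denominator yields 0 for that metric with
#' `degenerate = TRUE` and a warning, so batch evaluation survives
#' degenerate folds.
#'
#' @param counts a [confusion()] object or list with `TP`, `FP`, `TN`, `FN`.
#' @return list `precision`, `accuracy`, `recall`, `f1`, `counts`,
#'   `degenerate`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  n <- tp + fp + tn + fn
  if (n == 0) stop("all-zero confusion counts", call. = FALSE)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  if (degenerate) warning("zero denominator: affected metrics reported as 0")
  list(precision = precision,
       accuracy = (tp + tn) / n,
       recall = recall,
       f1 = f1,
       counts = counts,
       degenerate = degenerate)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= threshold`) and reports (FPR, TPR) points from (0, 0) to (1, 1).
#'
#' @param true_labels class labels; both classes must be present.
#' @param positive_scores numeric scores, higher meaning more positive.
#' @param positive_class label treated as positive.
#' @return list `points` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(true_labels, positive_scores, positive_class = "malignant") {
  if (length(true_labels) != length(positive_scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  if (!all(is.finite(positive_scores))) stop("scores must be finite", call. = FALSE)
  pos <- true_labels == positive_class
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes must be present", call. = FALSE)
  ord <- order(positive_scores, decreasing = TRUE)
  s <- positive_scores[ord]; y <- pos[ord]
  # cumulative counts at each distinct threshold (score ties collapse)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]; fp <- cumsum(!y)[last_of_tie]
  pts <- data.frame(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / nn),
    tpr = c(0, tp / np)
  )
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

#' Write metrics.json and roc.csv evaluation artifacts
#'
#' @param metrics a [compute_metrics()] result.
#' @param roc a [roc_curve()] result (optional).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_metrics <- function(metrics, roc = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(precision = metrics$precision, accuracy = metrics$accuracy,
              recall = metrics$recall, f1 = metrics$f1,
              counts = unclass(metrics$counts))
  if (!is.null(roc)) out$auc <- roc$auc
  jsonlite::write_json(out, file.path(dir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE)
  if (!is.null(roc)) {
    utils::write.csv(roc$points, file.path(dir, "roc.csv"), row.names = FALSE)
  }
  invisible(dir)
}
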