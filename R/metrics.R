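# Binary-classification evaluation: confusion counts at a probability
# threshold, sensitivity / specificity / accuracy / Matthews correlation,
# and the ROC curve with its area.

#' Confusion counts at a probability threshold
#'
#' A site is called positive iff its probability is strictly greater than
#' the threshold (so a probability of exactly 0.5 is a negative call at the
#' default threshold).
#'
#' @param labels Binary truth (0/1, logical, or `"positive"`/`"negative"`).
#' @param probabilities Predicted probabilities.
#' @param threshold Classification threshold (default 0.5).
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(labels, probabilities, threshold = 0.5) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(probabilities))
  call_pos <- probabilities > threshold
  c(TP = sum(call_pos & y == 1L), FP = sum(call_pos & y == 0L),
    TN = sum(!call_pos & y == 0L), FN = sum(!call_pos & y == 1L))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("positive", "negative")))
    return(as.integer(labels == "positive"))
  }
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)))
  y
}

#' Sensitivity: TP / (TP + FN)
#' @param counts Named counts from [confusion_counts()].
#' @return Numeric scalar.
#' @export
sensitivity <- function(counts) {
  unname(counts["TP"] / (counts["TP"] + counts["FN"]))
}

#' Specificity: TN / (TN + FP)
#' @inheritParams sensitivity
#' @return Numeric scalar.
#' @export
specificity <- function(counts) {
  unname(counts["TN"] / (counts["TN"] + counts["FP"]))
}

#' Accuracy: (TP + TN) / n
#' @inheritParams sensitivity
#' @return Numeric scalar.
#' @export
accuracy <- function(counts) {
  unname((counts["TP"] + counts["TN"]) / sum(counts))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))`; by convention 0
#' when any marginal is empty (zero denominator).
#'
#' @inheritParams sensitivity
#' @return Numeric scalar in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts["TP"]); tn <- as.numeric(counts["TN"])
  fp <- as.numeric(counts["FP"]); fn <- as.numeric(counts["FN"])
  den <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  if (den == 0) return(0)
  unname((tp * tn - fp * fn) / sqrt(den))
}

#' ROC curve and AUC
#'
#' The curve is traced over all distinct score thresholds and the area
#' computed by trapezoidal integration, which with the rank-average tie
#' handling equals the Mann-Whitney statistic: the probability that a
#' random positive outranks a random negative, counting ties as 1/2.
#'
#' @param labels Binary truth.
#' @param scores Real-valued scores (higher = more positive).
#' @return List with `auc` and a data frame `curve` of (`fpr`, `tpr`,
#'   `threshold`) points.
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  # collapse tied scores into single thresholds
  last_of_run <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- cumsum(ys)[last_of_run]
  fp <- cumsum(1 - ys)[last_of_run]
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                      threshold = c(Inf, ss[last_of_run]))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  list(auc = auc, curve = curve)
}

#' Standard evaluation report
#'
#' @param labels Binary truth.
#' @param probabilities Predicted probabilities.
#' @param threshold Classification threshold for the count-based metrics.
#' @return Named numeric vector `c(Sn, Sp, ACC, MCC, AUC)`.
#' @export
evaluation_report <- function(labels, probabilities, threshold = 0.5) {
  counts <- confusion_counts(labels, probabilities, threshold)
  c(Sn = sensitivity(counts), Sp = specificity(counts),
    ACC = accuracy(counts), MCC = mcc(counts),
    AUC = roc_auc(labels, probabilities)$auc)
}

#' Write an evaluation report and ROC points
#'
#' @param labels,probabilities,threshold As in [evaluation_report()].
#' @param path Output TSV for the metric row; ROC points are written next to
#'   it with suffix `.roc.tsv`.
#' @return The metric vector, invisibly.
#' @export
write_evaluation_report <- function(labels, probabilities, path,
                                    threshold = 0.5) {
  rep <- evaluation_report(labels, probabilities, threshold)
  write.table(as.data.frame(t(rep)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  roc <- roc_auc(labels, probabilities)
  write.table(roc$curve, paste0(path, ".roc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(rep)
}
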