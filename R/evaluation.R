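#' Multiclass confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns) over the
#' fixed class order.
#'
#' @param labels,predictions vectors of class labels (character/factor
#'   over `classes`, or integer indices).
#' @param classes class label order (default [psl_classes()]).
#' @return `K x K` integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(labels, predictions, classes = psl_classes()) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  to_factor <- function(v) {
    if (is.numeric(v)) v <- classes[as.integer(v)]
    v <- as.character(v)
    bad <- setdiff(unique(v), classes)
    if (length(bad))
      stop("unknown label(s): ", paste(bad, collapse = ", "))
    factor(v, levels = classes)
  }
  m <- table(true = to_factor(labels), predicted = to_factor(predictions))
  m <- unclass(m)
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' One-vs-rest reduction of a confusion matrix
#'
#' For the class at `class_index`: TP is the diagonal entry, FN the rest
#' of its row, FP the rest of its column, TN everything else. The four
#' counts always sum to the matrix total.
#'
#' @param matrix a square confusion matrix.
#' @param class_index class position (row/column index).
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
binary_counts <- function(matrix, class_index) {
  k <- nrow(matrix)
  stopifnot(class_index >= 1, class_index <= k)
  tp <- matrix[class_index, class_index]
  fn <- sum(matrix[class_index, ]) - tp
  fp <- sum(matrix[, class_index]) - tp
  tn <- sum(matrix) - tp - fn - fp
  list(TP = as.numeric(tp), TN = as.numeric(tn), FP = as.numeric(fp),
       FN = as.numeric(fn))
}

#' Binary classification metrics from counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' (sensitivity) `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' `F1 = 2*PR*RC/(PR+RC)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any
#' zero-denominator rate is reported as 0 (convention chosen so batch
#' evaluation never throws).
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN` (see
#'   [binary_counts()]).
#' @return named numeric vector `ACC`, `PR`, `RC`, `SP`, `F1`, `MCC`.
#' @export
binary_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  safe_div <- function(num, den) if (den > 0) num / den else 0
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  pr <- safe_div(tp, tp + fp)
  rc <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else 0
  c(ACC = acc, PR = pr, RC = rc, SP = sp, F1 = f1, MCC = mcc)
}

#' Macro-averaged multiclass metric report
#'
#' Per-class one-vs-rest metrics from the confusion matrix, their
#' unweighted (macro) means over all classes, plain top-1 accuracy (the
#' matrix trace over its total — reported alongside the macro-averaged
#' one-vs-rest accuracy because the two definitions differ in
#' multiclass problems), and, when a score matrix is supplied,
#' one-vs-rest AUC.
#'
#' @param matrix a [confusion()] matrix.
#' @param scores optional `n x K` probability matrix for AUC (requires
#'   `labels`).
#' @param labels labels matching `scores` rows.
#' @return a `metric_report` list with `per_class` (data frame), `macro`
#'   (named vector), `top1_accuracy`, `n`.
#' @export
macro_report <- function(matrix, scores = NULL, labels = NULL) {
  k <- nrow(matrix)
  per <- t(vapply(seq_len(k),
                  function(i) binary_metrics(binary_counts(matrix, i)),
                  numeric(6)))
  per <- as.data.frame(per)
  per$class <- rownames(matrix) %||% as.character(seq_len(k))
  per <- per[, c("class", "ACC", "PR", "RC", "SP", "F1", "MCC")]
  macro <- colMeans(per[, -1])
  if (!is.null(scores)) {
    auc <- auc_ovr(scores, labels,
                   classes = rownames(matrix) %||% colnames(scores))
    per$AUC <- auc$per_class
    macro <- c(macro, AUC = auc$macro)
  }
  structure(list(per_class = per, macro = macro,
                 top1_accuracy = sum(diag(matrix)) / sum(matrix),
                 n = sum(matrix)),
            class = "metric_report")
}

#' One-vs-rest AUC from class scores
#'
#' Rank-based (Mann-Whitney, equivalent to trapezoidal ROC integration)
#' area under the curve for each class against the rest, with tied
#' scores mid-ranked; the macro value is the unweighted mean over
#' classes that occur in the labels. Classes absent from the labels get
#' `NA` and are excluded from the macro with a warning.
#'
#' @param scores `n x K` matrix of class scores (e.g. softmax rows).
#' @param labels class labels of the `n` records.
#' @param classes class order matching the score columns.
#' @return list with `per_class` (named vector) and `macro`.
#' @export
auc_ovr <- function(scores, labels, classes = psl_classes()) {
  scores <- as.matrix(scores)
  if (is.numeric(labels)) labels <- classes[as.integer(labels)]
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(scores))
  per <- vapply(seq_along(classes), function(i) {
    pos <- labels == classes[i]
    npos <- sum(pos); nneg <- sum(!pos)
    if (npos == 0 || nneg == 0) return(NA_real_)
    r <- rank(scores[, i])
    (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  }, numeric(1))
  names(per) <- classes
  if (anyNA(per))
    warning("AUC undefined for class(es) absent from labels: ",
            paste(classes[is.na(per)], collapse = ", "))
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Multiclass metric report (n =", x$n, ")\n")
  cat("Top-1 accuracy:", round(x$top1_accuracy, 4), "\n")
  cat("Macro-averaged one-vs-rest metrics:\n")
  print(round(x$macro, 4))
  invisible(x)
}
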