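# Binary-classification metric suite -----------------------------------------

#' Confusion counts from labels and scores
#'
#' Predicted positive when score >= threshold (boundary counted positive).
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores/probabilities of the same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `confusion_counts` with TP, FP, TN, FN.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores) || length(labels) < 1) {
    stop("labels and scores must be equal-length, non-empty")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- scores >= threshold
  confusion_counts(TP = sum(pred & labels == 1),
                   FP = sum(pred & labels == 0),
                   TN = sum(!pred & labels == 0),
                   FN = sum(!pred & labels == 1))
}

#' @rdname confusion
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Metric suite from confusion counts
#'
#' Accuracy (TP+TN)/n, TPR TP/(TP+FN) (sensitivity is the same quantity),
#' precision TP/(TP+FP), specificity TN/(TN+FP), and the Matthews
#' correlation coefficient. Ratios with a zero denominator are NA; MCC is 0
#' when any marginal of the confusion matrix is zero.
#'
#' @param counts A `confusion_counts`.
#' @return A list of class `metric_report` with accuracy, tpr, sensitivity,
#'   precision, specificity, mcc (AUC, which needs scores, is computed by
#'   [auc_score()]).
#' @export
metric_suite <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  if (n < 1) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  marg <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(marg == 0)) 0 else {
    (TP * TN - FP * FN) / sqrt(prod(marg))
  }
  structure(list(
    accuracy = (TP + TN) / n,
    tpr = ratio(TP, TP + FN),
    sensitivity = ratio(TP, TP + FN),
    precision = ratio(TP, TP + FP),
    specificity = ratio(TN, TN + FP),
    mcc = mcc
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | TPR %.4f | precision %.4f | specificity %.4f | MCC %.4f\n",
              x$accuracy, x$tpr, x$precision, x$specificity, x$mcc))
  invisible(x)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores Numeric scores.
#' @return Scalar AUC in [0, 1].
#' @export
auc_score <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("AUC needs both classes present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Reconstruct confusion counts from summary rates
#'
#' Given class sizes and printed TPR/precision, recover integer counts:
#' TP = round(tpr * P), FP = round(TP * (1 - precision) / precision),
#' FN = P - TP, TN = N - FP (rounding to nearest, ties away from zero).
#'
#' @param P,N Positive and negative class sizes.
#' @param tpr True positive rate in (0, 1].
#' @param precision Precision in (0, 1].
#' @return A `confusion_counts`.
#' @export
counts_from_rates <- function(P, N, tpr, precision) {
  stopifnot(P > 0, N > 0, tpr > 0, tpr <= 1, precision > 0, precision <= 1)
  TP <- round_half_away(tpr * P)
  FP <- round_half_away(TP * (1 - precision) / precision)
  FN <- P - TP
  TN <- N - FP
  if (any(c(TP, FP, FN, TN) < 0)) {
    stop("rates are inconsistent with the class sizes (negative count)")
  }
  confusion_counts(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Write a metric report as a TSV row
#'
#' Column order mirrors the standard report table: AUC, Accuracy, TPR,
#' Precision, MCC, Pos_size, Neg_size.
#'
#' @param reports Named list: each element a list with fields auc, report
#'   (a `metric_report`), pos_size, neg_size.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metric_tsv <- function(reports, path) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(Data_set = nm, AUC = r$auc, Accuracy = r$report$accuracy,
               TPR = r$report$tpr, Precision = r$report$precision,
               MCC = r$report$mcc, Pos_size = r$pos_size,
               Neg_size = r$neg_size, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
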