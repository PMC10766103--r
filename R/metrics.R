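#' Confusion counts at a decision threshold
#'
#' Scores at or above the threshold are predicted positive (malignant).
#'
#' @param scores Positive-class probabilities.
#' @param labels Labels in \{0, 1\}.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels == 1),
                 FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0),
                 FN = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

#' Confusion counts from explicit values
#' @param TP,FP,TN,FN Nonnegative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  if (any(c(TP, FP, TN, FN) < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

#' Classification metrics from confusion counts
#'
#' The five standard confusion-matrix ratios, as percentages:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN).
#' A metric whose denominator is zero is reported as `NA` ("undefined"),
#' never silently as 0.
#'
#' @param cc A [confusion_counts()] object.
#' @return An object of class `metrics_report` with the five percentages and
#'   the counts; values carry full precision, the print method shows two
#'   decimals.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  structure(list(
    accuracy    = pct(cc$TP + cc$TN, cc$TP + cc$TN + cc$FP + cc$FN),
    sensitivity = pct(cc$TP, cc$TP + cc$FN),
    specificity = pct(cc$TN, cc$TN + cc$FP),
    ppv         = pct(cc$TP, cc$TP + cc$FP),
    npv         = pct(cc$TN, cc$TN + cc$FN),
    confusion   = cc, auc = NA_real_, roc_points = NULL),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat("<metrics_report>\n")
  cat(sprintf("  accuracy    %s\n  sensitivity %s\n  specificity %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity)))
  cat(sprintf("  PPV         %s\n  NPV         %s\n", fmt(x$ppv), fmt(x$npv)))
  if (!is.na(x$auc)) cat(sprintf("  AUC         %.3f\n", x$auc))
  cc <- x$confusion
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d\n", cc$TP, cc$FP, cc$TN,
              cc$FN))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC by the pairwise-concordance (rank) formulation: the probability that a
#' random positive outscores a random negative, ties counted 1/2. ROC points
#' are computed over all distinct score thresholds. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric scores.
#' @param labels Labels in \{0, 1\}; both classes must be present.
#' @return List with `auc` and `roc_points` (data.frame threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)           # midranks handle ties with weight 1/2
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0) / nneg,
      tpr = sum(pred & labels == 1) / npos)
  }, numeric(2)))
  list(auc = auc,
       roc_points = data.frame(threshold = thr, fpr = pts[, "fpr"],
                               tpr = pts[, "tpr"]))
}
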