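#' Pooled one-vs-rest counts from a multiclass confusion matrix
#'
#' Micro-averaging binarizes a `k`-class confusion matrix one class at a
#' time (class vs rest) and pools the four binary counts over all `k`
#' binarizations before any metric is computed. For a matrix with `N`
#' samples and trace `T` (correct predictions) the pooled counts are
#' `TP = T`, `FN = FP = N - T`, `TN = (k - 2) N + T`: every
#' misclassification is simultaneously a false negative for its true class
#' and a false positive for the predicted one, and a true negative for the
#' remaining `k - 2`. Consequently prevalence is exactly `1/k`, precision
#' equals recall (both `T/N`), and the false omission rate equals the
#' false-positive rate — the algebraic signature by which this aggregation
#' scheme is recognisable in a published metric table.
#'
#' @param confusion `k x k` (`k >= 2`) matrix of non-negative counts,
#'   rows = truth, columns = prediction (orientation does not matter).
#' @return A one-row tibble of class `binary_counts` with columns
#'   `TP`, `FP`, `FN`, `TN`, `k`, `N`.
#' @export
#' @examples
#' cm <- confusion_matrix(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 2, 0))
#' micro_ovr_counts(cm)  # TP 4, FP 2, FN 2, TN 10
micro_ovr_counts <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || nrow(confusion) < 2) {
    rlang::abort("confusion matrix must be square with k >= 2")
  }
  if (any(confusion < 0)) rlang::abort("confusion counts must be non-negative")
  k <- nrow(confusion)
  N <- sum(confusion)
  if (N == 0) rlang::abort("confusion matrix is empty")
  tr <- sum(diag(confusion))
  binary_counts(TP = tr, FP = N - tr, FN = N - tr, TN = (k - 2) * N + tr,
                k = k, N = N)
}

#' Assemble pooled one-vs-rest binary counts directly
#'
#' @param TP,FP,FN,TN Non-negative counts or proportions.
#' @param k,N Number of classes and samples, when known.
#' @return A one-row tibble of class `binary_counts`.
#' @export
binary_counts <- function(TP, FP, FN, TN, k = NA_integer_, N = NA_real_) {
  if (min(TP, FP, FN, TN) < 0 || TP + FP + FN + TN <= 0) {
    rlang::abort("binary counts must be non-negative with positive total")
  }
  out <- tibble::tibble(TP = as.double(TP), FP = as.double(FP),
                        FN = as.double(FN), TN = as.double(TN),
                        k = as.integer(k), N = as.double(N))
  class(out) <- c("binary_counts", class(out))
  out
}

#' Pooled counts implied by a multiclass accuracy
#'
#' Under micro one-vs-rest pooling every statistic is a function of the
#' multiclass accuracy `a` (the trace fraction) and the class count `k`
#' alone, so a printed accuracy or micro-precision determines the whole
#' battery. This inverts that map: per unit sample, `TP = a`,
#' `FN = FP = 1 - a`, `TN = k - 2 + a`.
#'
#' @param accuracy Multiclass accuracy (equivalently the micro-averaged
#'   precision or recall), in `[0, 1]`.
#' @param k Number of classes.
#' @param n Total sample count the proportions are scaled by.
#' @return A `binary_counts` row.
#' @export
#' @examples
#' metric_battery(counts_from_accuracy(0.80335, k = 8))
counts_from_accuracy <- function(accuracy, k, n = 1) {
  stopifnot(accuracy >= 0, accuracy <= 1, k >= 2)
  binary_counts(TP = accuracy * n, FP = (1 - accuracy) * n,
                FN = (1 - accuracy) * n, TN = ((k - 2) + accuracy) * n,
                k = k, N = n)
}

# Table-row order of the full battery.
metric_names <- c(
  "accuracy", "precision", "false_discovery_rate", "false_omission_rate",
  "negative_predictive_value", "prevalence", "recall",
  "false_positive_rate", "positive_likelihood_ratio", "false_negative_rate",
  "true_negative_rate", "negative_likelihood_ratio", "diagnostic_odds_ratio",
  "informedness", "markedness", "f_score", "g_measure",
  "matthews_correlation"
)

#' The full battery of confusion-derived statistics
#'
#' Computes all eighteen binary classification statistics from pooled
#' one-vs-rest counts: accuracy, precision (PPV), false discovery rate,
#' false omission rate, NPV, prevalence, recall (TPR), false-positive rate,
#' positive likelihood ratio (TPR/FPR), false-negative rate, specificity
#' (TNR), negative likelihood ratio (FNR/TNR), diagnostic odds ratio
#' (PLR/NLR), informedness (TPR + TNR - 1, Youden's J), markedness
#' (PPV + NPV - 1), F-score, G-measure (the geometric mean of precision and
#' recall), and the Matthews correlation coefficient.
#'
#' Zero denominators are never silently patched: a ratio with positive
#' numerator over zero is `Inf` (e.g. the diagnostic odds ratio of a
#' perfect classifier) and `0/0` is `NaN`, the battery's explicit
#' undefined marker.
#'
#' @param counts A `binary_counts` row ([micro_ovr_counts()],
#'   [counts_from_accuracy()], or [binary_counts()]).
#' @return A tibble of class `metric_report` with columns `metric` and
#'   `value`, rows in the canonical table order.
#' @export
metric_battery <- function(counts) {
  stopifnot(inherits(counts, "binary_counts"))
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  total <- TP + FP + FN + TN
  ppv <- TP / (TP + FP)
  npv <- TN / (TN + FN)
  tpr <- TP / (TP + FN)
  fpr <- FP / (FP + TN)
  tnr <- TN / (FP + TN)
  fnr <- FN / (TP + FN)
  plr <- tpr / fpr
  nlr <- fnr / tnr
  vals <- c(
    accuracy = (TP + TN) / total,
    precision = ppv,
    false_discovery_rate = FP / (TP + FP),
    false_omission_rate = FN / (TN + FN),
    negative_predictive_value = npv,
    prevalence = (TP + FN) / total,
    recall = tpr,
    false_positive_rate = fpr,
    positive_likelihood_ratio = plr,
    false_negative_rate = fnr,
    true_negative_rate = tnr,
    negative_likelihood_ratio = nlr,
    diagnostic_odds_ratio = plr / nlr,
    informedness = tpr + tnr - 1,
    markedness = ppv + npv - 1,
    f_score = 2 * ppv * tpr / (ppv + tpr),
    g_measure = sqrt(ppv * tpr),
    matthews_correlation = (TP * TN - FP * FN) /
      sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  )
  out <- tibble::tibble(metric = metric_names, value = unname(vals[metric_names]))
  class(out) <- c("metric_report", class(out))
  out
}

#' @export
print.metric_report <- function(x, digits = 5, ...) {
  cat("<metric_report>\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s %s\n", x$metric[i],
                formatC(x$value[i], format = "f", digits = digits)))
  }
  invisible(x)
}

#' Metric battery of a cross-validation result
#'
#' Convenience wrapper: pooled confusion -> micro one-vs-rest counts ->
#' [metric_battery()].
#'
#' @param cv A `cv_result` from [crossvalidate()].
#' @return A `metric_report` tibble.
#' @export
cv_metrics <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  metric_battery(micro_ovr_counts(cv$confusion))
}
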