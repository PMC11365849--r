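# Ranking and classification metrics with fold-level aggregation. The
# positive class throughout is "anomalous".

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative; tied scores count 1/2 (midrank convention).
#'
#' @param scores Numeric scores, larger = more anomalous.
#' @param labels Binary labels (1/TRUE = positive) of the same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores)                      # midranks handle ties
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision without interpolation: the mean, over
#' positives in score-descending order, of the precision at each positive's
#' rank.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1L)
  if (np == 0L) stop("at least one positive is required")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1L]) / np
}

#' F1 score on the positive class
#'
#' Harmonic mean of precision and recall; defined as 0 when there are no
#' true positives.
#'
#' @param predictions Binary predicted labels.
#' @param labels Binary reference labels.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(predictions, labels) {
  predictions <- as.integer(as.logical(predictions))
  labels <- as.integer(as.logical(labels))
  stopifnot(length(predictions) == length(labels))
  tp <- sum(predictions == 1L & labels == 1L)
  if (tp == 0L) return(0)
  prec <- tp / sum(predictions == 1L)
  rec <- tp / sum(labels == 1L)
  2 * prec * rec / (prec + rec)
}

#' Mean and Student-t confidence interval over folds
#'
#' `mean +- t_{n-1, (1+level)/2} * sd / sqrt(n)`.
#'
#' @param values Per-fold metric values (length >= 2).
#' @param level Confidence level.
#' @return Named vector `(mean, ci_low, ci_high)`.
#' @export
aggregate_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least two values to aggregate")
  m <- mean(values)
  hw <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  c(mean = m, ci_low = m - hw, ci_high = m + hw)
}

#' Aggregate per-fold metric triplets into a report
#'
#' @param per_fold data.frame with columns `auroc`, `auprc`, `f1` (one row
#'   per fold).
#' @param level Confidence level.
#' @param config Optional configuration fingerprint stored in the report.
#' @return A `metrics_report` with per-fold values and mean/CI per metric.
#' @export
metrics_report <- function(per_fold, level = 0.95, config = NULL) {
  stopifnot(all(c("auroc", "auprc", "f1") %in% names(per_fold)))
  agg <- lapply(c("auroc", "auprc", "f1"), function(m) aggregate_ci(per_fold[[m]], level))
  names(agg) <- c("auroc", "auprc", "f1")
  structure(list(per_fold = per_fold, aggregate = agg, level = level,
                 ci_method = "student-t over folds", config = config),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d folds, %g%% CI (%s)\n", nrow(x$per_fold),
              100 * x$level, x$ci_method))
  for (m in names(x$aggregate)) {
    a <- x$aggregate[[m]]
    cat(sprintf("  %-5s %.3f (%.3f-%.3f)\n", m, a["mean"], a["ci_low"], a["ci_high"]))
  }
  invisible(x)
}
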