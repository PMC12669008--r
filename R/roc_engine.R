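# Decision rule used throughout: a record is predicted "pathology" when its
# score is >= the threshold t (so t = 0 is the all-positive corner and every
# observed score is attainable as a cut-off). A strict ">" variant is
# available via the `rule` argument.

#' Predict labels at a threshold
#'
#' @param cohort A `scored_cohort`.
#' @param t Threshold in \[0, 1\].
#' @param rule `"ge"` (default, score >= t is positive) or `"gt"`.
#' @return Integer vector of predicted labels.
#' @export
predict_at_threshold <- function(cohort, t, rule = c("ge", "gt")) {
  stopifnot(inherits(cohort, "scored_cohort"))
  rule <- match.arg(rule)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1) {
    stop("threshold must be a single number in [0, 1]", call. = FALSE)
  }
  if (rule == "ge") as.integer(cohort$scores >= t) else as.integer(cohort$scores > t)
}

#' Confusion counts at one threshold
#'
#' @inheritParams predict_at_threshold
#' @return An object of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `n`, `threshold`.
#' @examples
#' coh <- scored_cohort(c(0.8, 0.6, 0.4, 0.7, 0.3, 0.1), c(1, 1, 1, 0, 0, 0))
#' confusion_at_threshold(coh, 0.5)
#' @export
confusion_at_threshold <- function(cohort, t, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  pred <- predict_at_threshold(cohort, t, rule)
  lab <- cohort$labels
  structure(
    list(tp = sum(pred == 1L & lab == 1L),
         fp = sum(pred == 1L & lab == 0L),
         tn = sum(pred == 0L & lab == 0L),
         fn = sum(pred == 0L & lab == 1L),
         n = cohort$n, threshold = t),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts at t = %g (n = %d)\n", x$threshold, x$n))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("pathology", "normal"),
                              predicted = c("pathology", "normal")))
  print(m)
  invisible(x)
}

# Vectorised confusion sweep: counts at many thresholds via sorted scores.
# count(s >= t) = length(s) - #(s < t), the latter from findInterval with a
# left-open convention. Cross-checked against the naive count in the tests.
sweep_counts <- function(cohort, thresholds) {
  s_pos <- sort(cohort$scores[cohort$labels == 1L])
  s_neg <- sort(cohort$scores[cohort$labels == 0L])
  tp <- length(s_pos) - findInterval(thresholds, s_pos, left.open = TRUE)
  fp <- length(s_neg) - findInterval(thresholds, s_neg, left.open = TRUE)
  data.frame(threshold = thresholds, tp = tp, fp = fp,
             tn = length(s_neg) - fp, fn = length(s_pos) - tp)
}

#' Sensitivity, specificity, accuracy from confusion counts
#'
#' Se = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/n. A ratio with an empty
#' denominator (a degenerate class) is reported as `NaN` with a warning,
#' never silently zero, so batch reports survive degenerate strata.
#'
#' @param counts A `confusion_counts` object.
#' @return An object of class `diagnostic_metrics`: `se`, `sp`, `acc`.
#' @examples
#' diagnostic_metrics(confusion_at_threshold(
#'   scored_cohort(c(0.9, 0.1), c(1, 0)), 0.5))
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_pos <- counts$tp + counts$fn
  n_neg <- counts$tn + counts$fp
  se <- if (n_pos > 0L) counts$tp / n_pos else {
    warning("sensitivity undefined: no positive records", call. = FALSE)
    NaN
  }
  sp <- if (n_neg > 0L) counts$tn / n_neg else {
    warning("specificity undefined: no negative records", call. = FALSE)
    NaN
  }
  structure(list(se = se, sp = sp, acc = (counts$tp + counts$tn) / counts$n),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("Se = %.4f  Sp = %.4f  Acc = %.4f\n", x$se, x$sp, x$acc))
  invisible(x)
}

#' Empirical ROC curve
#'
#' Candidate thresholds are the unique observed scores plus an `Inf` sentinel
#' (the (0, 0) corner); the curve therefore passes exactly through every
#' operating point attainable on the data. AUC is the trapezoidal area over
#' (FPR, TPR), which equals the Mann-Whitney pair-counting statistic with
#' half credit for ties.
#'
#' @param cohort A `scored_cohort` with at least one record of each class.
#' @param rule Decision rule, see [predict_at_threshold()].
#' @return An object of class `nb_roc`: `thresholds` (strictly decreasing,
#'   starting at `Inf`), `fpr`, `tpr` (both non-decreasing), `auc`, `n_pos`,
#'   `n_neg`.
#' @examples
#' roc_curve(scored_cohort(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)))$auc
#' @export
roc_curve <- function(cohort, rule = c("ge", "gt")) {
  stopifnot(inherits(cohort, "scored_cohort"))
  rule <- match.arg(rule)
  if (cohort$n_pos == 0L || cohort$n_neg == 0L) {
    stop("ROC (and AUC) are undefined for a single-class cohort: need at least one pathology and one normal record",
         call. = FALSE)
  }
  thr <- c(Inf, sort(unique(cohort$scores), decreasing = TRUE))
  cnt <- if (rule == "ge") {
    sweep_counts(cohort, thr)
  } else {
    # score > t is equivalent to score >= next-representable(t); just count directly
    data.frame(threshold = thr,
               tp = vapply(thr, function(t) sum(cohort$scores > t & cohort$labels == 1L), 0L),
               fp = vapply(thr, function(t) sum(cohort$scores > t & cohort$labels == 0L), 0L))
  }
  fpr <- cnt$fp / cohort$n_neg
  tpr <- cnt$tp / cohort$n_pos
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = cohort$n_pos, n_neg = cohort$n_neg),
            class = "nb_roc")
}

#' @export
print.nb_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f (%d pathology / %d normal)\n",
              length(x$thresholds), x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
as.data.frame.nb_roc <- function(x, ...) {
  data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}

#' Export an ROC curve as CSV
#'
#' @param roc An `nb_roc` object.
#' @param path Output path; columns `threshold`, `fpr`, `tpr`.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "nb_roc"))
  utils::write.csv(as.data.frame(roc), path, row.names = FALSE)
  invisible(path)
}
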