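# Threshold-selection strategies. All selectors return a `threshold_selection`
# object and are reproducible by exhaustive search over the candidate
# threshold set (asserted in the test suite).

new_selection <- function(method, threshold, criterion_value, cohort = NULL,
                          details = list()) {
  metrics <- if (!is.null(cohort)) {
    diagnostic_metrics(confusion_at_threshold(cohort, min(max(threshold, 0), 1)))
  } else NULL
  structure(list(method = method, threshold = threshold,
                 criterion_value = criterion_value, metrics = metrics,
                 details = details),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("Threshold selection [%s]: t = %.4g (criterion = %.4g)\n",
              x$method, x$threshold, x$criterion_value))
  if (!is.null(x$metrics)) {
    cat("  "); print(x$metrics)
  }
  invisible(x)
}

#' Threshold probability implied by losses and profits
#'
#' In decision-curve analysis the threshold probability pt at which treating
#' and not treating break even satisfies pt/(1-pt) = L/P, i.e.
#' pt = L/(L+P), where L is the loss from treating a healthy individual and
#' P the profit from treating a sick one.
#'
#' @param L,P Positive reals.
#' @return pt in (0, 1).
#' @examples
#' loss_threshold(L = 1, P = 4) # 0.2
#' @export
loss_threshold <- function(L, P) {
  if (!is.numeric(L) || !is.numeric(P) || length(L) != 1L || length(P) != 1L ||
      is.na(L) || is.na(P) || L <= 0 || P <= 0) {
    stop("L and P must be positive numbers", call. = FALSE)
  }
  L / (L + P)
}

#' Classical (decision-curve) net benefit at a threshold probability
#'
#' NB(pt) = TP/n - FP/n * pt/(1-pt), with counts taken at the decision
#' threshold pt itself.
#'
#' @param cohort A `scored_cohort`.
#' @param pt Threshold probability in (0, 1).
#' @return The net benefit (a real; prevalence is its upper bound).
#' @export
net_benefit <- function(cohort, pt) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (!is.numeric(pt) || length(pt) != 1L || is.na(pt) || pt <= 0 || pt >= 1) {
    stop("pt must lie strictly inside (0, 1)", call. = FALSE)
  }
  cc <- confusion_at_threshold(cohort, pt)
  cc$tp / cc$n - cc$fp / cc$n * pt / (1 - pt)
}

selector_grid <- function(roc) {
  # candidate thresholds from an ROC sweep; drop the Inf sentinel for
  # reporting purposes only when a finite candidate achieves the optimum.
  data.frame(threshold = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr)
}

pick_best <- function(g, crit, maximize = TRUE) {
  # tie-break: best criterion, then highest sensitivity, then smallest
  # threshold (screening favours detection; deterministic output)
  v <- if (maximize) crit else -crit
  cand <- which(v == max(v))
  cand <- cand[order(-g$tpr[cand], g$threshold[cand])]
  cand[1L]
}

#' Youden-index threshold
#'
#' Maximizes J = Se + Sp - 1 = TPR - FPR over the candidate thresholds of an
#' ROC curve. Ties are broken towards the highest sensitivity, then the
#' smallest threshold.
#'
#' @param roc An `nb_roc` object from [roc_curve()].
#' @param cohort The cohort the curve was built from (used to attach
#'   diagnostic metrics at the selected threshold); optional.
#' @return A `threshold_selection` with `criterion_value` = J at the optimum.
#' @export
youden_threshold <- function(roc, cohort = NULL) {
  stopifnot(inherits(roc, "nb_roc"))
  g <- selector_grid(roc)
  i <- pick_best(g, g$tpr - g$fpr)
  t_star <- min(g$threshold[i], 1)
  new_selection("youden", t_star, g$tpr[i] - g$fpr[i], cohort,
                details = list(tpr = g$tpr[i], fpr = g$fpr[i]))
}

#' Closest-to-(0,1) threshold
#'
#' Minimizes the Euclidean distance d = sqrt((1-TPR)^2 + FPR^2) from the
#' perfect-classifier corner to the ROC curve.
#'
#' @inheritParams youden_threshold
#' @return A `threshold_selection` with `criterion_value` = d at the optimum.
#' @export
closest_topleft_threshold <- function(roc, cohort = NULL) {
  stopifnot(inherits(roc, "nb_roc"))
  g <- selector_grid(roc)
  d <- sqrt((1 - g$tpr)^2 + g$fpr^2)
  i <- pick_best(g, d, maximize = FALSE)
  new_selection("closest_topleft", min(g$threshold[i], 1), d[i], cohort,
                details = list(tpr = g$tpr[i], fpr = g$fpr[i]))
}

#' Fixed-sensitivity threshold
#'
#' Returns the largest threshold whose sensitivity still reaches
#' `target_se`, i.e. maximizes specificity subject to a sensitivity floor.
#' `target_se = 1` yields the smallest positive score (no missed pathology).
#'
#' @param cohort A `scored_cohort` with at least one positive record.
#' @param target_se Required sensitivity in (0, 1\].
#' @return A `threshold_selection` with `criterion_value` = attained Se.
#' @export
fixed_sensitivity_threshold <- function(cohort, target_se) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (!is.numeric(target_se) || length(target_se) != 1L || is.na(target_se) ||
      target_se <= 0 || target_se > 1) {
    stop("target_se must lie in (0, 1]", call. = FALSE)
  }
  if (cohort$n_pos == 0L) {
    stop("fixed-sensitivity selection needs at least one positive record",
         call. = FALSE)
  }
  thr <- sort(unique(cohort$scores), decreasing = TRUE)
  cnt <- sweep_counts(cohort, thr)
  se <- cnt$tp / cohort$n_pos
  ok <- which(se >= target_se)
  i <- ok[1L] # thresholds descend, so the first qualifying one is largest
  new_selection("fixed_sensitivity", thr[i], se[i], cohort,
                details = list(target_se = target_se))
}

#' Fixed-specificity threshold
#'
#' Symmetric counterpart of [fixed_sensitivity_threshold()]: the smallest
#' threshold whose specificity still reaches `target_sp` (maximize
#' sensitivity subject to a specificity floor).
#'
#' @param cohort A `scored_cohort` with at least one negative record.
#' @param target_sp Required specificity in (0, 1\].
#' @return A `threshold_selection` with `criterion_value` = attained Sp.
#' @export
fixed_specificity_threshold <- function(cohort, target_sp) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (!is.numeric(target_sp) || length(target_sp) != 1L || is.na(target_sp) ||
      target_sp <= 0 || target_sp > 1) {
    stop("target_sp must lie in (0, 1]", call. = FALSE)
  }
  if (cohort$n_neg == 0L) {
    stop("fixed-specificity selection needs at least one negative record",
         call. = FALSE)
  }
  thr <- sort(unique(cohort$scores), decreasing = TRUE)
  cnt <- sweep_counts(cohort, thr)
  sp <- cnt$tn / cohort$n_neg
  ok <- which(sp >= target_sp)
  if (!length(ok)) {
    # every observed cut-off misclassifies too many normals; the sentinel
    # "above all scores" always attains sp = 1
    t_star <- 1
    return(new_selection("fixed_specificity", t_star, 1, cohort,
                         details = list(target_sp = target_sp)))
  }
  i <- ok[length(ok)] # thresholds descend; last qualifying one is smallest
  new_selection("fixed_specificity", thr[i], sp[i], cohort,
                details = list(target_sp = target_sp))
}

#' NetBenefit0 / NetBenefit1 curve pair
#'
#' Two modified net-benefit curves over a common threshold axis t, with
#' weight w(p) = p/(1-p):
#' \deqn{NB_0(t) = TP(t)/n - TN(t)/n \cdot w(p_0)}
#' \deqn{NB_1(t) = FP(t)/n - FN(t)/n \cdot w(p_1)}
#' NB0 rewards correct recognition of both classes; NB1 tracks the two error
#' types. By default both weight probabilities equal the sweep threshold
#' itself (p0 = p1 = t, one common x-axis); fixed `p0`/`p1` values (e.g.
#' from [loss_threshold()]) may be supplied instead.
#'
#' With `weights = "observed"` the counts are the cohort's raw confusion
#' counts, so NB0(0) = prevalence and NB1(0) = 1 - prevalence. With
#' `weights = "balanced"` the two classes are reweighted to equal size
#' (counts replaced by per-class rates times n/2) before the curves are
#' formed: the deterministic analogue of subsampling to equal classes, which
#' is what makes an intersection exist on heavily imbalanced screening
#' cohorts (see the package vignette for the existence condition).
#'
#' @param cohort A `scored_cohort`.
#' @param grid Strictly increasing thresholds in \[0, 1-eps\]; default is
#'   1,001 evenly spaced points on \[0, 0.999\] united with the cohort's
#'   unique scores (eps = 1e-3 guards the w(t) singularity at t = 1).
#' @param p0,p1 Optional fixed weight probabilities in \[0, 1); `NULL`
#'   (default) means "use the sweep threshold t".
#' @param weights `"observed"` (default) or `"balanced"`.
#' @return An object of class `nb_curves`: a data frame with columns
#'   `threshold`, `nb0`, `nb1` and attributes `n`, `prevalence`, `weights`.
#' @export
net_benefit_curves <- function(cohort, grid = NULL, p0 = NULL, p1 = NULL,
                               weights = c("observed", "balanced")) {
  stopifnot(inherits(cohort, "scored_cohort"))
  weights <- match.arg(weights)
  eps <- 1e-3
  if (is.null(grid)) {
    grid <- sort(unique(c(seq(0, 1 - eps, length.out = 1001L),
                          cohort$scores[cohort$scores <= 1 - eps])))
  } else {
    grid <- sort(unique(as.numeric(grid)))
    if (any(!is.finite(grid)) || any(grid < 0) || any(grid >= 1)) {
      stop("grid thresholds must lie in [0, 1): the weight t/(1-t) diverges at 1",
           call. = FALSE)
    }
  }
  for (p in list(p0, p1)) {
    if (!is.null(p) && (!is.numeric(p) || length(p) != 1L || is.na(p) ||
                        p < 0 || p >= 1)) {
      stop("fixed p0/p1 must be a single probability in [0, 1)", call. = FALSE)
    }
  }
  cnt <- sweep_counts(cohort, grid)
  n <- cohort$n
  if (weights == "balanced") {
    if (cohort$n_pos == 0L || cohort$n_neg == 0L) {
      stop("balanced weighting needs both classes present", call. = FALSE)
    }
    half <- n / 2
    tp <- cnt$tp / cohort$n_pos * half
    fn <- cnt$fn / cohort$n_pos * half
    fp <- cnt$fp / cohort$n_neg * half
    tn <- cnt$tn / cohort$n_neg * half
  } else {
    tp <- cnt$tp; fp <- cnt$fp; tn <- cnt$tn; fn <- cnt$fn
  }
  w0 <- if (is.null(p0)) grid / (1 - grid) else p0 / (1 - p0)
  w1 <- if (is.null(p1)) grid / (1 - grid) else p1 / (1 - p1)
  out <- data.frame(threshold = grid,
                    nb0 = tp / n - tn / n * w0,
                    nb1 = fp / n - fn / n * w1)
  structure(out, class = c("nb_curves", "data.frame"),
            n = n, prevalence = cohort$n_pos / n, weights = weights,
            p0 = p0, p1 = p1)
}

#' Export a net-benefit curve pair as CSV
#'
#' @param curves An `nb_curves` object.
#' @param path Output path; columns `threshold`, `nb0`, `nb1`.
#' @return `path`, invisibly.
#' @export
write_nb_curves <- function(curves, path) {
  stopifnot(inherits(curves, "nb_curves"))
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}

# strict sign changes of D between consecutive non-zero values; an exact
# zero flanked by opposite non-zero signs counts as a root at that grid
# point. Leading/trailing zero plateaus and sign "touches" are not crossings.
find_crossings <- function(t, D) {
  nz <- which(D != 0)
  roots <- numeric(0)
  # interior exact zeros flanked by opposite signs
  zi <- which(D == 0)
  for (i in zi) {
    lo <- nz[nz < i]; hi <- nz[nz > i]
    if (length(lo) && length(hi) &&
        sign(D[lo[length(lo)]]) != sign(D[hi[1L]])) {
      roots <- c(roots, t[i])
    }
  }
  # sign flips between consecutive non-zero grid values with no zero between
  if (length(nz) > 1L) {
    for (k in seq_len(length(nz) - 1L)) {
      i <- nz[k]; j <- nz[k + 1L]
      if (j == i + 1L && sign(D[i]) != sign(D[j])) {
        # linear interpolation inside the bracketing interval
        roots <- c(roots, t[i] - D[i] * (t[j] - t[i]) / (D[j] - D[i]))
      }
    }
  }
  sort(unique(roots))
}

#' Net-benefit intersection threshold
#'
#' The decision threshold is the x-coordinate where the NetBenefit0 and
#' NetBenefit1 curves intersect: the point of maximum overall benefit, where
#' the balance tips between rewarding correct recognitions and penalizing
#' the two error types. The root of D(t) = NB0(t) - NB1(t) is located by a
#' strict sign change on the grid and refined by linear interpolation within
#' the first bracketing interval (counts are step functions, so no iterative
#' solver is warranted). If several crossings exist the smallest-t one is
#' returned -- the most sensitivity-preserving choice in screening -- with a
#' warning listing all of them.
#'
#' @param curves An `nb_curves` object (grid of at least 3 points).
#' @param cohort Optional `scored_cohort` used to attach diagnostic metrics
#'   at the selected threshold.
#' @return A `threshold_selection`; `criterion_value` is NB0 at the
#'   crossing, `details$crossings` lists every crossing found.
#' @export
nb_intersection_threshold <- function(curves, cohort = NULL) {
  stopifnot(inherits(curves, "nb_curves"))
  if (nrow(curves) < 3L) {
    stop("need a grid of at least 3 points to locate an intersection",
         call. = FALSE)
  }
  t <- curves$threshold
  D <- curves$nb0 - curves$nb1
  crossings <- find_crossings(t, D)
  if (!length(crossings)) {
    stop(paste0(
      "no intersection between NetBenefit0 and NetBenefit1 on the grid; ",
      "widen or refine the grid, or -- on heavily imbalanced cohorts, where ",
      "no crossing can exist for raw counts -- use weights = \"balanced\" ",
      "(see ?net_benefit_curves)"), call. = FALSE)
  }
  if (length(crossings) > 1L) {
    warning(sprintf("multiple NB0/NB1 crossings at t = %s; returning the smallest",
                    paste(signif(crossings, 4), collapse = ", ")),
            call. = FALSE)
  }
  t_star <- crossings[1L]
  nb0_star <- stats::approx(t, curves$nb0, xout = t_star, ties = "ordered")$y
  new_selection("nb_intersection", t_star, nb0_star, cohort,
                details = list(crossings = crossings,
                               weights = attr(curves, "weights")))
}
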