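# Fixtures are built in code, and every non-trivial expectation has an
# independent oracle: naive loops, pair counting, exhaustive search over the
# candidate thresholds, or closed-form recomputation.

make_cohort <- function(pos, neg) {
  scored_cohort(c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))))
}

# six-record cohort used repeatedly across the suite
six_cohort <- function() make_cohort(c(0.8, 0.6, 0.4), c(0.7, 0.3, 0.1))

random_cohort <- function(n, prevalence = 0.4, ties = FALSE) {
  labels <- stats::rbinom(n, 1L, prevalence)
  scores <- if (ties) {
    sample(seq(0.05, 0.95, by = 0.05), n, replace = TRUE) +
      0.04 * labels * sample(0:1, n, replace = TRUE)
  } else {
    stats::plogis(stats::rnorm(n, 1.2 * labels, 1))
  }
  scored_cohort(pmin(pmax(scores, 0), 1), labels)
}

# naive per-record confusion counts
oracle_confusion <- function(cohort, t) {
  pred <- as.integer(cohort$scores >= t)
  list(tp = sum(pred == 1 & cohort$labels == 1),
       fp = sum(pred == 1 & cohort$labels == 0),
       tn = sum(pred == 0 & cohort$labels == 0),
       fn = sum(pred == 0 & cohort$labels == 1))
}

# Mann-Whitney pair counting, ties half credit
oracle_auc <- function(cohort) {
  s1 <- cohort$scores[cohort$labels == 1L]
  s0 <- cohort$scores[cohort$labels == 0L]
  cmp <- outer(s1, s0, ">") + 0.5 * outer(s1, s0, "==")
  mean(cmp)
}

# candidate thresholds of the >= rule: unique scores plus a sentinel above all
oracle_candidates <- function(cohort) c(Inf, sort(unique(cohort$scores),
                                                  decreasing = TRUE))

oracle_se_sp <- function(cohort, t) {
  cc <- oracle_confusion(cohort, t)
  c(se = cc$tp / cohort$n_pos, sp = cc$tn / cohort$n_neg,
    fpr = cc$fp / cohort$n_neg)
}

# exhaustive-search selectors with the package's documented tie-breaks
# (best criterion, then highest sensitivity, then smallest threshold).
# criteria are expressed in (tpr, fpr) so that exact float ties resolve the
# same way in both routes
oracle_best <- function(cohort, crit_fun, maximize = TRUE) {
  cand <- oracle_candidates(cohort)
  rows <- t(vapply(cand, function(t) {
    m <- oracle_se_sp(cohort, t)
    c(t = t, se = m[["se"]], crit = crit_fun(m[["se"]], m[["fpr"]]))
  }, numeric(3)))
  v <- if (maximize) rows[, "crit"] else -rows[, "crit"]
  best <- which(v == max(v))
  best <- best[order(-rows[best, "se"], rows[best, "t"])]
  list(threshold = unname(min(rows[best[1L], "t"], 1)),
       crit = unname(rows[best[1L], "crit"]))
}

oracle_youden <- function(cohort) {
  oracle_best(cohort, function(tpr, fpr) tpr - fpr)
}
oracle_closest <- function(cohort) {
  oracle_best(cohort, function(tpr, fpr) sqrt((1 - tpr)^2 + fpr^2),
              maximize = FALSE)
}
oracle_fixed_se <- function(cohort, target) {
  cand <- sort(unique(cohort$scores), decreasing = TRUE)
  for (t in cand) {
    if (oracle_se_sp(cohort, t)[["se"]] >= target) return(t)
  }
  stop("unreachable")
}

# scalar net-benefit recomputation at one grid point
oracle_nb_point <- function(cohort, t, balanced = FALSE) {
  cc <- oracle_confusion(cohort, t)
  n <- cohort$n
  if (balanced) {
    cc <- list(tp = cc$tp / cohort$n_pos * n / 2,
               fn = cc$fn / cohort$n_pos * n / 2,
               fp = cc$fp / cohort$n_neg * n / 2,
               tn = cc$tn / cohort$n_neg * n / 2)
  }
  w <- t / (1 - t)
  c(nb0 = cc$tp / n - cc$tn / n * w, nb1 = cc$fp / n - cc$fn / n * w)
}

# a near-balanced, well-separated screening-validation cohort on which the
# NB0/NB1 curves are guaranteed to cross under observed counts
crossing_cohort <- function(n = 10000, seed = 11, prevalence = 0.45,
                            sep = 2.5) {
  generate_cohort(synthetic_spec(
    n, prevalence, "binormal_logistic",
    list(mu0 = -sep / 2, mu1 = sep / 2, sigma0 = 1, sigma1 = 1), seed = seed))
}
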