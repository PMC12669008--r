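test_that("loss-profile threshold probability is L/(L+P)", {
  expect_equal(loss_threshold(1, 4), 0.2)
  expect_equal(loss_threshold(2, 2), 0.5)
  expect_equal(loss_threshold(3, 1), 0.75)
  expect_error(loss_threshold(0, 1), "positive")
  expect_error(loss_threshold(1, -2), "positive")
})

test_that("classical net benefit matches its defining formula", {
  # weight pt/(1-pt) = 1 at pt = 0.5: NB = (TP - FP)/n
  coh <- make_cohort(c(rep(0.9, 30), rep(0.1, 10)),
                     c(rep(0.8, 10), rep(0.2, 50)))
  expect_equal(net_benefit(coh, 0.5), (30 - 10) / 100)
  expect_equal(net_benefit(six_cohort(), 0.5), 1 / 6)
  # pt -> 0: weight vanishes and everything is predicted positive
  expect_equal(net_benefit(coh, 1e-9), coh$n_pos / coh$n, tolerance = 1e-6)
  expect_error(net_benefit(coh, 0), "\\(0, 1\\)")
  expect_error(net_benefit(coh, 1), "\\(0, 1\\)")

  set.seed(13)
  for (i in 1:10) {
    coh <- random_cohort(50)
    pt <- runif(1, 0.05, 0.95)
    cc <- oracle_confusion(coh, pt)
    expect_equal(net_benefit(coh, pt),
                 (cc$tp - cc$fp * pt / (1 - pt)) / coh$n)
  }
})

test_that("Youden selector maximizes J with the documented tie-breaks", {
  coh <- six_cohort()
  sel <- youden_threshold(roc_curve(coh), coh)
  expect_equal(sel$threshold, 0.4)
  expect_equal(sel$criterion_value, 2 / 3)
  # J equals tpr - fpr at the selected point
  m <- oracle_se_sp(coh, sel$threshold)
  expect_equal(sel$criterion_value, m[["se"]] + m[["sp"]] - 1)

  sepa <- make_cohort(c(0.9, 0.7, 0.6), c(0.5, 0.4, 0.2))
  sels <- youden_threshold(roc_curve(sepa), sepa)
  expect_equal(sels$threshold, 0.6)
  expect_equal(sels$criterion_value, 1)

  # uninformative scores: J* near zero
  set.seed(8)
  rnd <- scored_cohort(runif(4000), sample(rep(0:1, 2000)))
  expect_lt(youden_threshold(roc_curve(rnd))$criterion_value, 0.08)

  # tie in J resolved towards higher sensitivity, then smaller threshold
  tie <- make_cohort(c(0.9, 0.3), c(0.6, 0.1))  # J = 1/2 at t in {0.9, 0.3}
  selt <- youden_threshold(roc_curve(tie), tie)
  expect_equal(selt$threshold, 0.3)
  expect_equal(selt$details$tpr, 1)
})

test_that("closest-to-corner selector minimizes the distance to (0,1)", {
  sep <- make_cohort(rep(0.9, 3), rep(0.1, 4))
  sel <- closest_topleft_threshold(roc_curve(sep), sep)
  expect_equal(sel$criterion_value, 0)
  expect_equal(sel$metrics$se, 1)
  expect_equal(sel$metrics$sp, 1)

  coh <- six_cohort()
  o <- oracle_closest(coh)
  sel6 <- closest_topleft_threshold(roc_curve(coh), coh)
  expect_equal(sel6$threshold, o$threshold)
  expect_equal(sel6$criterion_value, o$crit)
  m <- oracle_se_sp(coh, sel6$threshold)
  expect_equal(sel6$criterion_value^2, (1 - m[["se"]])^2 + (1 - m[["sp"]])^2)
})

test_that("fixed-sensitivity selector takes the largest threshold meeting the floor", {
  coh <- six_cohort()
  sel <- fixed_sensitivity_threshold(coh, 0.66)
  expect_equal(sel$threshold, 0.6)
  expect_equal(oracle_se_sp(coh, sel$threshold)[c("se", "sp")],
               c(se = 2 / 3, sp = 2 / 3))
  # a floor just above 2/3 forces the threshold down to 0.4 (se = 1)
  sel2 <- fixed_sensitivity_threshold(coh, 0.67)
  expect_equal(sel2$threshold, 0.4)
  expect_equal(sel2$criterion_value, 1)
  # 100% sensitivity: threshold at the smallest positive score, no misses
  sel3 <- fixed_sensitivity_threshold(coh, 1)
  expect_equal(sel3$threshold, min(coh$scores[coh$labels == 1]))
  expect_equal(confusion_at_threshold(coh, sel3$threshold)$fn, 0L)
  expect_error(fixed_sensitivity_threshold(coh, 1.1), "\\(0, 1\\]")

  sp_sel <- fixed_specificity_threshold(coh, 0.66)
  expect_equal(oracle_se_sp(coh, sp_sel$threshold)[["sp"]], 2 / 3)
})

test_that("selectors are reproducible by exhaustive search over candidates", {
  set.seed(31)
  for (i in 1:30) {
    coh <- random_cohort(sample(20:200, 1), prevalence = runif(1, 0.2, 0.6),
                         ties = i %% 3 == 0)
    if (coh$n_pos == 0 || coh$n_neg == 0) next
    roc <- roc_curve(coh)
    expect_equal(youden_threshold(roc)$threshold, oracle_youden(coh)$threshold)
    expect_equal(closest_topleft_threshold(roc)$threshold,
                 oracle_closest(coh)$threshold)
    target <- runif(1, 0.5, 1)
    expect_equal(fixed_sensitivity_threshold(coh, target)$threshold,
                 oracle_fixed_se(coh, target))
  }
})

test_that("net-benefit curves satisfy their boundary and unit-weight identities", {
  set.seed(17)
  for (i in 1:8) {
    coh <- random_cohort(80, prevalence = runif(1, 0.1, 0.6))
    cv <- net_benefit_curves(coh)
    expect_equal(cv$threshold[1], 0)
    expect_equal(cv$nb0[1], class_prevalence(coh))       # NB0(0) = prevalence
    expect_equal(cv$nb1[1], 1 - class_prevalence(coh))   # NB1(0) = 1 - prevalence
    # t = 0.5 has weight 1 (explicit grid: the default one need not contain 1/2)
    cc <- oracle_confusion(coh, 0.5)
    cv5 <- net_benefit_curves(coh, grid = c(0.25, 0.5, 0.75))
    expect_equal(cv5$nb0[2], (cc$tp - cc$tn) / coh$n)
    expect_equal(cv5$nb1[2], (cc$fp - cc$fn) / coh$n)
    # towards t = 1 the weight diverges and both curves plunge
    expect_lt(cv$nb0[nrow(cv)], -1)
  }
})

test_that("net-benefit curves match scalar recomputation on a coarse grid", {
  coh <- six_cohort()
  grid <- seq(0.05, 0.95, by = 0.05)
  cv <- net_benefit_curves(coh, grid = grid)
  for (j in seq_along(grid)) {
    o <- oracle_nb_point(coh, grid[j])
    expect_equal(cv$nb0[j], o[["nb0"]])
    expect_equal(cv$nb1[j], o[["nb1"]])
  }
  # balanced weighting: same identity with per-class-rescaled counts
  cvb <- net_benefit_curves(coh, grid = grid, weights = "balanced")
  for (j in seq_along(grid)) {
    o <- oracle_nb_point(coh, grid[j], balanced = TRUE)
    expect_equal(cvb$nb0[j], o[["nb0"]])
    expect_equal(cvb$nb1[j], o[["nb1"]])
  }
  expect_error(net_benefit_curves(coh, grid = c(0.5, 1)), "\\[0, 1\\)")
})

test_that("fixed weight probabilities p0/p1 override the sweep threshold", {
  coh <- six_cohort()
  grid <- c(0.2, 0.5, 0.8)
  cv <- net_benefit_curves(coh, grid = grid, p0 = 0.25, p1 = 0.75)
  w0 <- 0.25 / 0.75
  w1 <- 3
  for (j in seq_along(grid)) {
    cc <- oracle_confusion(coh, grid[j])
    expect_equal(cv$nb0[j], (cc$tp - cc$tn * w0) / 6)
    expect_equal(cv$nb1[j], (cc$fp - cc$fn * w1) / 6)
  }
  expect_error(net_benefit_curves(coh, p0 = 1), "p0/p1")
})

test_that("intersection threshold finds the first sign change and interpolates", {
  # balanced six-record cohort: NB0 - NB1 = (TP - FP)(1 - w)/n, root at 0.5
  coh <- six_cohort()
  sel <- nb_intersection_threshold(net_benefit_curves(coh), coh)
  expect_equal(sel$threshold, 0.5, tolerance = 1e-4)

  # the root is bracketed by a strict sign change on the grid
  cv <- net_benefit_curves(crossing_cohort(4000, seed = 2))
  sel2 <- suppressWarnings(nb_intersection_threshold(cv))
  D <- cv$nb0 - cv$nb1
  i <- max(which(cv$threshold <= sel2$threshold & D != 0))
  j <- min(which(cv$threshold > sel2$threshold & D != 0))
  expect_true(sign(D[i]) != sign(D[j]))
  # interpolated curves meet at the root
  nb0_at <- approx(cv$threshold, cv$nb0, sel2$threshold)$y
  nb1_at <- approx(cv$threshold, cv$nb1, sel2$threshold)$y
  expect_equal(nb0_at, nb1_at, tolerance = 1e-10)
  expect_equal(sel2$criterion_value, nb0_at)

  # several crossings: smallest returned, all reported
  expect_warning(s3 <- nb_intersection_threshold(cv), "multiple")
  expect_gte(length(s3$details$crossings), 2)
  expect_equal(s3$threshold, min(s3$details$crossings))

  expect_error(
    nb_intersection_threshold(net_benefit_curves(coh, grid = c(0.1, 0.2))),
    "at least 3")
})

test_that("no intersection exists for raw counts on rare-pathology cohorts", {
  # with prevalence p, a crossing of D(t) = [(TP-FP)(1-w) - w(n_neg-n_pos)]/n
  # needs t/(1-2t) < p/(1-2p); at p = 0.029 no realistic classifier crosses
  coh <- generate_cohort(preset_service_profiles(n = 5000)$service_A)
  expect_error(nb_intersection_threshold(net_benefit_curves(coh), coh),
               "no intersection")
  # the equal-class reweighting restores a crossing, pinned at t = 1/2
  selb <- nb_intersection_threshold(
    net_benefit_curves(coh, weights = "balanced"), coh)
  expect_equal(selb$threshold, 0.5, tolerance = 1e-4)
})

test_that("on near-balanced cohorts the intersection is more sensitive than Youden", {
  # directional check of the method's purpose: the first NB0/NB1 crossing
  # sits below the Youden point, trading specificity for sensitivity
  for (seed in 1:10) {
    coh <- crossing_cohort(8000, seed = seed)
    roc <- roc_curve(coh)
    y <- youden_threshold(roc, coh)
    nb <- suppressWarnings(
      nb_intersection_threshold(net_benefit_curves(coh), coh))
    expect_gt(nb$metrics$se, y$metrics$se)
    expect_lt(nb$metrics$sp, y$metrics$sp)
    mt <- mcnemar_test(paired_table(predict_at_threshold(coh, y$threshold),
                                    predict_at_threshold(coh, nb$threshold)))
    expect_lt(mt$p_value, 0.05)
  }
})
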