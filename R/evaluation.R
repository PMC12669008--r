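# Paired evaluation of thresholding strategies: 2x2 agreement tables,
# McNemar tests, strategy comparison reports, and cross-model aggregates.

#' Cross-tabulate two binary prediction sequences
#'
#' @param pred_ref,pred_alt Equal-length vectors of 0/1 values; `pred_ref`
#'   is the reference rater (e.g. ground truth, or the Youden-threshold
#'   predictions when comparing strategies).
#' @return An object of class `paired_dichotomy`: concordant counts
#'   `both_pos`, `both_neg` and discordant counts `b` (ref positive, alt
#'   negative) and `c` (ref negative, alt positive).
#' @examples
#' paired_table(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
paired_table <- function(pred_ref, pred_alt) {
  r <- suppressWarnings(as.integer(pred_ref))
  a <- suppressWarnings(as.integer(pred_alt))
  if (length(r) != length(a)) {
    stop(sprintf("sequences differ in length (%d vs %d)", length(r), length(a)),
         call. = FALSE)
  }
  if (any(is.na(r)) || any(is.na(a)) ||
      !all(r %in% c(0L, 1L)) || !all(a %in% c(0L, 1L))) {
    stop("both sequences must contain only 0/1 values", call. = FALSE)
  }
  structure(list(both_pos = sum(r == 1L & a == 1L),
                 b = sum(r == 1L & a == 0L),
                 c = sum(r == 0L & a == 1L),
                 both_neg = sum(r == 0L & a == 0L),
                 n = length(r)),
            class = "paired_dichotomy")
}

#' @export
print.paired_dichotomy <- function(x, ...) {
  m <- matrix(c(x$both_pos, x$c, x$b, x$both_neg), 2, 2,
              dimnames = list(reference = c("pos", "neg"),
                              comparator = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' McNemar test on a paired dichotomy
#'
#' Tests marginal homogeneity of two paired binary raters using only the
#' discordant counts (b, c). With `method = "auto"` (the common textbook
#' rule) the exact two-sided binomial test on (b, b + c, 1/2) is used when
#' b + c < 25, and the continuity-corrected chi-square
#' \eqn{(\max(0, |b-c|-1))^2/(b+c)} with 1 df otherwise. b + c = 0 gives
#' p = 1 by convention.
#'
#' @param table A `paired_dichotomy` from [paired_table()].
#' @param method `"auto"`, `"exact_binomial"`, or `"chi_square_cc"`.
#' @return An object of class `mcnemar_result`: `statistic` (NA for the
#'   exact method), `p_value`, `method`, `b`, `c`.
#' @examples
#' mcnemar_test(paired_table(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' @export
mcnemar_test <- function(table, method = c("auto", "exact_binomial",
                                           "chi_square_cc")) {
  stopifnot(inherits(table, "paired_dichotomy"))
  method <- match.arg(method)
  b <- table$b; cc <- table$c; m <- b + cc
  if (method == "auto") {
    method <- if (m < 25L) "exact_binomial" else "chi_square_cc"
  }
  if (m == 0L) {
    return(structure(list(statistic = if (method == "chi_square_cc") 0 else NA_real_,
                          p_value = 1, method = method, b = b, c = cc),
                     class = "mcnemar_result"))
  }
  if (method == "exact_binomial") {
    p <- min(1, 2 * stats::pbinom(min(b, cc), m, 0.5))
    stat <- NA_real_
  } else {
    stat <- (max(0, abs(b - cc) - 1))^2 / m
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p, method = method, b = b, c = cc),
            class = "mcnemar_result")
}

#' Format a p-value the way screening reports print it
#'
#' Four significant figures with a display floor of "< 0.0001".
#'
#' @param p A p-value in \[0, 1\].
#' @return A character scalar.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "< 0.0001", formatC(signif(p, 4), format = "fg"))
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar test (%s): b = %d, c = %d, %sp = %s\n",
              x$method, x$b, x$c,
              if (is.na(x$statistic)) "" else sprintf("chi2 = %.4g, ", x$statistic),
              format_p(x$p_value)))
  invisible(x)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Compare thresholding strategies on one cohort
#'
#' Runs the requested selectors on the cohort, derives per-strategy
#' predictions and diagnostic metrics, and performs McNemar tests of each
#' strategy's predictions against the ground-truth labels as well as of the
#' net-benefit predictions against the Youden predictions taken as
#' reference. Reported metrics are rounded to 2 decimals in the table while
#' full precision is retained in the `selections`.
#'
#' @param cohort A `scored_cohort` with both classes present.
#' @param strategies Subset of `c("youden", "nb_intersection")`.
#' @param nb_weights Passed to [net_benefit_curves()] (`"observed"` or
#'   `"balanced"`).
#' @param grid Optional threshold grid for the net-benefit curves.
#' @param mcnemar_method Passed to [mcnemar_test()].
#' @return An object of class `comparison_report`.
#' @export
compare_strategies <- function(cohort,
                               strategies = c("youden", "nb_intersection"),
                               nb_weights = "observed",
                               grid = NULL,
                               mcnemar_method = "auto") {
  stopifnot(inherits(cohort, "scored_cohort"))
  strategies <- match.arg(strategies, c("youden", "nb_intersection"),
                          several.ok = TRUE)
  if (cohort$n_pos == 0L || cohort$n_neg == 0L) {
    stop("strategy comparison needs both classes present", call. = FALSE)
  }

  selections <- list()
  if ("youden" %in% strategies) {
    roc <- roc_curve(cohort)
    selections$youden <- youden_threshold(roc, cohort)
  }
  if ("nb_intersection" %in% strategies) {
    curves <- net_benefit_curves(cohort, grid = grid, weights = nb_weights)
    selections$nb_intersection <- tryCatch(
      nb_intersection_threshold(curves, cohort),
      error = function(e) {
        stop(sprintf("net-benefit strategy failed on this cohort: %s",
                     conditionMessage(e)), call. = FALSE)
      })
  }

  predictions <- lapply(selections, function(s) {
    predict_at_threshold(cohort, s$threshold)
  })

  metrics_table <- do.call(rbind, lapply(names(selections), function(nm) {
    s <- selections[[nm]]
    data.frame(strategy = nm,
               threshold = round(s$threshold, 4),
               se = round(s$metrics$se, 2),
               sp = round(s$metrics$sp, 2),
               acc = round(s$metrics$acc, 2))
  }))

  mcnemar_vs_truth <- lapply(predictions, function(p) {
    mcnemar_test(paired_table(cohort$labels, p), method = mcnemar_method)
  })
  mcnemar_nb_vs_youden <- NULL
  if (all(c("youden", "nb_intersection") %in% names(predictions))) {
    mcnemar_nb_vs_youden <- mcnemar_test(
      paired_table(predictions$youden, predictions$nb_intersection),
      method = mcnemar_method)
  }

  structure(
    list(n = cohort$n, prevalence = class_prevalence(cohort),
         strategies = names(selections),
         selections = selections,
         metrics_table = metrics_table,
         mcnemar_vs_truth = mcnemar_vs_truth,
         mcnemar_nb_vs_youden = mcnemar_nb_vs_youden,
         n_tests = length(mcnemar_vs_truth) +
           (!is.null(mcnemar_nb_vs_youden)),
         nb_weights = if ("nb_intersection" %in% strategies) nb_weights else NULL),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Strategy comparison on %d records (prevalence %.4f)\n",
              x$n, x$prevalence))
  print(x$metrics_table, row.names = FALSE)
  for (nm in names(x$mcnemar_vs_truth)) {
    cat(sprintf("  %s vs ground truth: p %s\n", nm,
                sub("^<", "<", format_p(x$mcnemar_vs_truth[[nm]]$p_value))))
  }
  if (!is.null(x$mcnemar_nb_vs_youden)) {
    cat(sprintf("  nb_intersection vs youden (reference): p %s\n",
                format_p(x$mcnemar_nb_vs_youden$p_value)))
  }
  cat(sprintf("  (%d McNemar tests performed; no multiplicity correction applied)\n",
              x$n_tests))
  invisible(x)
}

report_to_list <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  sel <- lapply(report$selections, function(s) {
    list(method = s$method, threshold = s$threshold,
         criterion_value = s$criterion_value,
         se = s$metrics$se, sp = s$metrics$sp, acc = s$metrics$acc)
  })
  mc <- lapply(report$mcnemar_vs_truth, function(m) {
    list(method = m$method, b = m$b, c = m$c,
         statistic = m$statistic, p_value = m$p_value,
         p_display = format_p(m$p_value))
  })
  out <- list(n = report$n, prevalence = report$prevalence,
              strategies = report$strategies,
              selections = sel, mcnemar_vs_truth = mc,
              n_tests = report$n_tests)
  if (!is.null(report$mcnemar_nb_vs_youden)) {
    m <- report$mcnemar_nb_vs_youden
    out$mcnemar_nb_vs_youden <- list(method = m$method, b = m$b, c = m$c,
                                     statistic = m$statistic,
                                     p_value = m$p_value,
                                     p_display = format_p(m$p_value))
  }
  out
}

#' Serialize a comparison report as JSON
#'
#' The JSON layout is described by the schema shipped at
#' `system.file("schema", "comparison_report.schema.json", package = "nbthreshold")`.
#'
#' @param report A `comparison_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Render a comparison report as a Markdown table
#'
#' @param report A `comparison_report`.
#' @return A character vector of Markdown lines.
#' @export
report_to_markdown <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  m <- report$metrics_table
  lines <- c("| Strategy | Threshold | Se | Sp | Acc | p vs ground truth |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(m))) {
    p <- format_p(report$mcnemar_vs_truth[[m$strategy[i]]]$p_value)
    lines <- c(lines, sprintf("| %s | %.4g | %.2f | %.2f | %.2f | %s |",
                              m$strategy[i], m$threshold[i], m$se[i],
                              m$sp[i], m$acc[i], p))
  }
  if (!is.null(report$mcnemar_nb_vs_youden)) {
    lines <- c(lines, "",
               sprintf("McNemar, net-benefit vs Youden predictions as reference: p %s",
                       format_p(report$mcnemar_nb_vs_youden$p_value)))
  }
  lines
}

#' Aggregate diagnostic metrics across models
#'
#' Computes the arithmetic mean, minimum and maximum of sensitivity,
#' specificity and accuracy across a set of models (one row per model), per
#' strategy -- the usual way a multi-service evaluation summarizes its
#' per-service tables. Values are reported both as raw fractions and as
#' whole percents (round-half-away-from-zero, the convention of printed
#' clinical tables).
#'
#' @param metrics A data frame with columns `strategy`, `se`, `sp`, `acc`
#'   (one row per model/version), e.g. built from several
#'   `comparison_report$metrics_table`s.
#' @return A data frame with one row per strategy and metric: columns
#'   `strategy`, `metric`, `mean`, `min`, `max`, `mean_pct`, `min_pct`,
#'   `max_pct`.
#' @examples
#' tab <- data.frame(strategy = "youden",
#'                   se = c(0.53, 0.68, 0.72), sp = c(0.84, 0.81, 0.84),
#'                   acc = c(0.83, 0.81, 0.84))
#' summarize_across_models(tab)
#' @export
summarize_across_models <- function(metrics) {
  metrics <- as.data.frame(metrics)
  need <- c("strategy", "se", "sp", "acc")
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols)) {
    stop(sprintf("metrics table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(metrics) == 0L) {
    stop("metrics table is empty", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(metrics, metrics$strategy), function(d) {
    do.call(rbind, lapply(c("se", "sp", "acc"), function(m) {
      v <- d[[m]]
      data.frame(strategy = d$strategy[1L], metric = m,
                 mean = mean(v), min = min(v), max = max(v))
    }))
  }))
  rownames(out) <- NULL
  for (col in c("mean", "min", "max")) {
    out[[paste0(col, "_pct")]] <- round_half_away(out[[col]] * 100)
  }
  out
}
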