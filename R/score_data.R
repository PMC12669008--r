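#' Construct a scored screening cohort
#'
#' A scored cohort is the universal input of this package: one classifier
#' score per subject (a "pathology probability" in \[0, 1\]) together with a
#' binary ground-truth label (1 = pathology, 0 = normal). Scores of exactly 0
#' or 1 are legal; saturating AI services do emit them.
#'
#' @param scores Numeric vector of classifier scores, each in \[0, 1\].
#' @param labels Vector coercible to integer, each element 0 or 1.
#' @param ids Optional vector of opaque subject identifiers, same length.
#' @return An object of class `scored_cohort`: a list with elements
#'   `scores`, `labels`, `ids`, `n`, `n_pos`, `n_neg`.
#' @examples
#' coh <- scored_cohort(c(0.9, 0.2, 0.5), c(1, 0, 0))
#' coh$n_pos
#' @export
scored_cohort <- function(scores, labels, ids = NULL) {
  scores <- as.numeric(scores)
  labels_raw <- labels
  labels <- suppressWarnings(as.integer(labels_raw))
  n <- length(scores)
  if (n < 1L) {
    stop("a cohort needs at least one record", call. = FALSE)
  }
  if (length(labels) != n) {
    stop(sprintf("scores (%d) and labels (%d) differ in length",
                 n, length(labels)), call. = FALSE)
  }
  if (!is.null(ids) && length(ids) != n) {
    stop("ids must match the number of records", call. = FALSE)
  }
  bad <- which(!is.finite(scores) | scores < 0 | scores > 1)
  if (length(bad)) {
    stop(sprintf("scores must lie in [0, 1]; offending record(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  bad <- which(is.na(labels) | !(labels %in% c(0L, 1L)))
  if (length(bad)) {
    stop(sprintf("labels must be 0 or 1; offending record(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  structure(
    list(scores = scores, labels = labels, ids = ids,
         n = n, n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)),
    class = "scored_cohort"
  )
}

#' @export
print.scored_cohort <- function(x, ...) {
  cat(sprintf("Scored cohort: %d records (%d pathology, %d normal; prevalence %.4f)\n",
              x$n, x$n_pos, x$n_neg, x$n_pos / x$n))
  cat(sprintf("  score range: [%.4g, %.4g]\n", min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
as.data.frame.scored_cohort <- function(x, ...) {
  d <- data.frame(score = x$scores, label = x$labels)
  if (!is.null(x$ids)) d <- cbind(id = x$ids, d)
  d
}

#' Binarize BI-RADS categories into pathology labels
#'
#' BI-RADS (Breast Imaging Reporting and Data System) categories 1-3 map to
#' "normal" (0) and categories 4-6 to "pathology" (1). Category 0 flags an
#' incomplete/erroneous evaluation and is excluded: it maps to `NA`, and
#' callers are expected to drop and count such records (as [read_cohort()]
#' does).
#'
#' @param birads Integer vector with values in `0:6`.
#' @return Integer vector of the same length: 0, 1, or `NA` (excluded).
#' @examples
#' binarize_birads(c(4, 3, 0))
#' @export
binarize_birads <- function(birads) {
  b <- suppressWarnings(as.integer(birads))
  bad <- which(is.na(b) | b != as.numeric(birads) | b < 0L | b > 6L)
  if (length(bad)) {
    stop(sprintf("BI-RADS category must be an integer in 0..6; got %s at position %d",
                 deparse(birads[bad[1L]]), bad[1L]), call. = FALSE)
  }
  out <- integer(length(b))
  out[b >= 1L & b <= 3L] <- 0L
  out[b >= 4L] <- 1L
  out[b == 0L] <- NA_integer_
  out
}

#' Read a scored cohort from CSV
#'
#' The file must have a header, a numeric score column, and either a binary
#' label column or a BI-RADS column (binarized via [binarize_birads()];
#' category-0 records are dropped and counted). Row order is preserved.
#' Missing or non-numeric scores are a hard error, never imputed.
#'
#' @param path Path to a CSV file (comma separator, header, UTF-8).
#' @param score_col,label_col,birads_col Column names; the label column wins
#'   when both label and BI-RADS columns are present.
#' @return A `scored_cohort`. When a BI-RADS column was used, the attribute
#'   `"exclusions"` holds `list(n_excluded, rows)` for the dropped
#'   category-0 records (data row numbers, 1-based).
#' @export
read_cohort <- function(path, score_col = "score", label_col = "label",
                        birads_col = "birads") {
  if (!file.exists(path)) {
    stop(sprintf("no such file: %s", path), call. = FALSE)
  }
  d <- utils::read.csv(path, colClasses = "character",
                       check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(d) == 0L) {
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  }
  if (!score_col %in% names(d)) {
    stop(sprintf("%s: missing score column '%s'", path, score_col),
         call. = FALSE)
  }
  has_label <- label_col %in% names(d)
  has_birads <- birads_col %in% names(d)
  if (!has_label && !has_birads) {
    stop(sprintf("%s: need a '%s' or '%s' column", path, label_col, birads_col),
         call. = FALSE)
  }

  scores <- suppressWarnings(as.numeric(d[[score_col]]))
  bad <- which(is.na(scores))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric or missing score at data row(s) %s",
                 path, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(scores < 0 | scores > 1)
  if (length(bad)) {
    stop(sprintf("%s: score outside [0, 1] at data row(s) %s (first value %s)",
                 path, paste(utils::head(bad, 5L), collapse = ", "),
                 d[[score_col]][bad[1L]]), call. = FALSE)
  }

  exclusions <- NULL
  if (has_label) {
    labels <- suppressWarnings(as.integer(d[[label_col]]))
    bad <- which(is.na(labels) | !(labels %in% c(0L, 1L)))
    if (length(bad)) {
      stop(sprintf("%s: label not in {0, 1} at data row(s) %s",
                   path, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
  } else {
    birads <- suppressWarnings(as.numeric(d[[birads_col]]))
    bad <- which(is.na(birads))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric BI-RADS at data row(s) %s",
                   path, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
    labels <- binarize_birads(birads)
    drop <- which(is.na(labels))
    exclusions <- list(n_excluded = length(drop), rows = drop)
    if (length(drop)) {
      keep <- setdiff(seq_len(nrow(d)), drop)
      if (!length(keep)) {
        stop(sprintf("%s: all records are BI-RADS 0 (excluded)", path),
             call. = FALSE)
      }
      scores <- scores[keep]
      labels <- labels[keep]
      d <- d[keep, , drop = FALSE]
    }
  }

  ids <- if ("id" %in% names(d)) d[["id"]] else NULL
  coh <- scored_cohort(scores, labels, ids = ids)
  if (!is.null(exclusions)) attr(coh, "exclusions") <- exclusions
  coh
}

#' Write a scored cohort to CSV
#'
#' Scores are printed with `%.17g` so that a written cohort re-reads to
#' bit-identical doubles (and a second write is byte-identical to the first).
#'
#' @param cohort A `scored_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "scored_cohort"))
  d <- data.frame(score = sprintf("%.17g", cohort$scores),
                  label = cohort$labels)
  if (!is.null(cohort$ids)) d <- cbind(id = cohort$ids, d)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Class prevalence of a cohort
#'
#' @param cohort A `scored_cohort`.
#' @return The fraction of pathology (label 1) records, `n_pos / n`.
#' @examples
#' class_prevalence(scored_cohort(c(0.8, 0.1), c(1, 0)))
#' @export
class_prevalence <- function(cohort) {
  stopifnot(inherits(cohort, "scored_cohort"))
  cohort$n_pos / cohort$n
}
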