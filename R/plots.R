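# ggplot2 figures: ROC curve with selected operating points, and the
# NetBenefit0/NetBenefit1 chart with the intersection threshold marked.

#' Plot an ROC curve with selected thresholds marked
#'
#' @param roc An `nb_roc` object.
#' @param selections Optional named list of `threshold_selection` objects;
#'   each is drawn as a labelled point on the curve.
#' @return A ggplot object.
#' @export
plot_roc_curve <- function(roc, selections = list()) {
  stopifnot(inherits(roc, "nb_roc"))
  d <- as.data.frame(roc)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_path(colour = "#2c7fb8", linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity (FPR)", y = "Sensitivity (TPR)",
                  title = sprintf("ROC curve (AUC = %.3f)", roc$auc)) +
    ggplot2::theme_minimal()
  if (length(selections)) {
    pts <- do.call(rbind, lapply(selections, function(s) {
      data.frame(method = s$method,
                 fpr = 1 - s$metrics$sp, tpr = s$metrics$se,
                 label = sprintf("%s (t = %.2f)", s$method, s$threshold))
    }))
    p <- p +
      ggplot2::geom_point(data = pts, ggplot2::aes(colour = .data$method),
                          size = 2.5) +
      ggplot2::geom_text(data = pts,
                         ggplot2::aes(label = .data$label, colour = .data$method),
                         hjust = -0.05, vjust = 1.4, size = 3,
                         show.legend = FALSE) +
      ggplot2::labs(colour = "strategy")
  }
  p
}

#' Plot the NetBenefit0/NetBenefit1 curve pair
#'
#' @param curves An `nb_curves` object.
#' @param selection Optional `threshold_selection` from
#'   [nb_intersection_threshold()]; drawn as a vertical line at the
#'   intersection.
#' @param ylim Optional y-axis limits (the curves diverge towards -Inf as
#'   t approaches 1, so a window is often wanted).
#' @return A ggplot object.
#' @export
plot_nb_curves <- function(curves, selection = NULL, ylim = NULL) {
  stopifnot(inherits(curves, "nb_curves"))
  d <- rbind(data.frame(threshold = curves$threshold, value = curves$nb0,
                        curve = "NetBenefit0"),
             data.frame(threshold = curves$threshold, value = curves$nb1,
                        curve = "NetBenefit1"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$value,
                                       colour = .data$curve)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Decision threshold t", y = "Net benefit",
                  colour = NULL,
                  title = "NetBenefit0 / NetBenefit1 curves") +
    ggplot2::theme_minimal()
  if (!is.null(selection)) {
    p <- p +
      ggplot2::geom_vline(xintercept = selection$threshold,
                          linetype = "dashed", colour = "grey30") +
      ggplot2::annotate("text", x = selection$threshold, y = Inf,
                        label = sprintf("t* = %.3f", selection$threshold),
                        vjust = 1.5, hjust = -0.1, size = 3)
  }
  if (!is.null(ylim)) p <- p + ggplot2::coord_cartesian(ylim = ylim)
  p
}
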