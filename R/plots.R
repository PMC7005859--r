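#' Plot fragment XICs
#'
#' Line plot of extracted ion chromatograms, one colour per fragment.
#'
#' @param xics Long tibble with columns `fragment`, `rt`, `intensity`.
#' @param peak_groups Optional [detect_peak_groups()] output; boundaries are
#'   drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_xics <- function(xics, peak_groups = NULL) {
  p <- ggplot2::ggplot(xics, ggplot2::aes(.data$rt, .data$intensity,
                                          colour = .data$fragment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Retention time (s)", y = "Intensity",
                  colour = "Fragment") +
    ggplot2::theme_minimal()
  if (!is.null(peak_groups) && nrow(peak_groups) > 0L) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(peak_groups$left, peak_groups$right),
                          linetype = "dashed", colour = "grey50")
  }
  p
}

#' @rdname localize_precursor
#' @param object A `site_localization` object.
#' @method autoplot site_localization
#' @export
autoplot.site_localization <- function(object, ...) {
  d <- dplyr::mutate(object$sites,
                     label = paste0(.data$residue, .data$position))
  ggplot2::ggplot(d, ggplot2::aes(.data$label, .data$confidence,
                                  fill = .data$class1)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
                               name = "Class I") +
    ggplot2::labs(
      x = "Candidate residue", y = "Site confidence",
      title = sprintf("%s (%d+)", object$peptide$sequence, object$charge)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname fit_3dmm
#' @param object An `occupancy_fit`.
#' @method autoplot occupancy_fit
#' @export
autoplot.occupancy_fit <- function(object, ...) {
  ggplot2::ggplot(object$occupancy,
                  ggplot2::aes(.data$condition, .data$occupancy)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Condition", y = "Occupancy",
                  title = sprintf("alpha = %.3g, beta = %.3g",
                                  object$alpha, object$beta)) +
    ggplot2::theme_minimal()
}

#' @rdname roc_from_scores
#' @param object A `roc_curve`.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Boxplot of estimated fold changes by condition
#'
#' Companion plot for the mixed-species ratio benchmark: the distribution of
#' per-feature estimated fold changes for the regulated subpopulation per
#' condition, with the design ratio marked.
#'
#' @param fold_changes Output of [estimate_fold_changes()] restricted or not
#'   to regulated features (requires `true_ratio`).
#' @return A ggplot object.
#' @export
plot_ratio_benchmark <- function(fold_changes) {
  ggplot2::ggplot(fold_changes,
                  ggplot2::aes(factor(.data$true_ratio),
                               log2(.data$fold_change))) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_point(
      ggplot2::aes(y = log2(.data$true_ratio)),
      colour = "red", shape = 4, size = 3,
      data = dplyr::distinct(fold_changes, .data$true_ratio)
    ) +
    ggplot2::labs(x = "Design ratio", y = "log2 estimated fold change") +
    ggplot2::theme_minimal()
}
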