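#' Volcano plot of a differential-abundance table
#'
#' @param results a `diff_table` from [differential_table()].
#' @param p_threshold,fdr_threshold significance lines/colors.
#' @param label_top number of most significant proteins to label.
#' @return A ggplot.
#' @export
plot_volcano <- function(results, p_threshold = 0.05, fdr_threshold = 0.05,
                         label_top = 7) {
  dat <- results |>
    dplyr::mutate(status = dplyr::case_when(
      .data$fdr < fdr_threshold ~ "FDR significant",
      .data$p_value < p_threshold ~ "p < threshold",
      TRUE ~ "not significant"))
  lab <- utils::head(dplyr::arrange(dat, .data$p_value), label_top)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_fc,
                                    y = -log10(.data$p_value),
                                    color = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$protein),
                       vjust = -0.6, size = 2.8, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(
      "FDR significant" = "#c0392b", "p < threshold" = "#2980b9",
      "not significant" = "grey60")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 permutation p", color = NULL) +
    ggplot2::theme_minimal()
}

# empirical ROC coordinates from scores/labels
.roc_coords <- function(scores, y) {
  th <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  tibble::tibble(
    tpr = vapply(th, function(t) mean(scores[y == 1] >= t), numeric(1)),
    fpr = vapply(th, function(t) mean(scores[y == 0] >= t), numeric(1))
  )
}

#' ROC curves for a selected panel
#'
#' Draws the cross-validated ROC curve of the final panel next to that of
#' the top single marker.
#'
#' @param object a `panel_fit` from [select_panel()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot panel_fit
#' @export
autoplot.panel_fit <- function(object, ...) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(.roc_coords(object$cv_scores, object$labels),
                  model = sprintf("panel (%s), AUROC %.2f",
                                  paste(object$panel, collapse = "+"),
                                  object$auroc_panel$auc)),
    dplyr::mutate(.roc_coords(object$single_scores, object$labels),
                  model = sprintf("%s alone, AUROC %.2f", object$panel[1],
                                  object$auroc_single$auc)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$fpr, .data$tpr, color = .data$model)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom", legend.direction = "vertical")
}

#' Per-protein SRM summary box plots
#'
#' Case/control distributions of the median-polish per-sample summaries.
#'
#' @param object an `srm_result` from [srm_group_compare()].
#' @param proteins optional subset of proteins to show.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot srm_result
#' @export
autoplot.srm_result <- function(object, proteins = NULL, ...) {
  dat <- attr(object, "sample_summaries")
  if (!is.null(proteins)) dat <- dplyr::filter(dat, .data$protein %in% proteins)
  ggplot2::ggplot(dat, ggplot2::aes(.data$group, .data$log2_summary,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~protein, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "normalized log2 light/heavy summary") +
    ggplot2::theme_minimal()
}
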