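#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve plot for a performance estimate
#'
#' Median bootstrap ROC curve with the chance diagonal and the operating
#' point implied by the positivity threshold (median sensitivity and
#' 1 - specificity) marked with dashed guides.
#'
#' @param object A `performance_summary` from [estimate_performance()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot performance_summary
#' @export
autoplot.performance_summary <- function(object, ...) {
  pt <- stats::setNames(object$summary$point, object$summary$metric)
  op <- data.frame(fpr = 1 - pt[["specificity"]], tpr = pt[["sensitivity"]])
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = op$fpr, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = op$tpr, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(data = op, size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = "AR vs STABLE, median bootstrap ROC",
      subtitle = sprintf("AUROC %.2f (%.2f-%.2f); threshold %.1f%%",
                         pt[["auroc"]],
                         object$summary$ci_low[object$summary$metric == "auroc"],
                         object$summary$ci_high[object$summary$metric == "auroc"],
                         object$threshold_pct)
    ) +
    ggplot2::theme_minimal()
}

#' Box plot of dd-cfDNA fractions by diagnostic cohort
#'
#' @param samples Samples tibble with `sample_id` and
#'   `corrected_fraction_pct`.
#' @param labels Labels tibble from [assign_cohorts()]; excluded samples are
#'   dropped.
#' @param threshold_pct Positivity threshold drawn as a reference line
#'   (default 1.0).
#' @return A ggplot (log10 fraction scale).
#' @export
plot_cohort_fractions <- function(samples, labels, threshold_pct = 1.0) {
  df <- dplyr::inner_join(samples,
                          dplyr::select(labels, "sample_id", "label"),
                          by = "sample_id") |>
    dplyr::filter(.data$label != "EXCLUDED") |>
    dplyr::mutate(label = factor(.data$label, levels = cohort_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label,
                                   y = .data$corrected_fraction_pct)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold_pct, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Corrected dd-cfDNA fraction (%)",
                  title = "dd-cfDNA by diagnostic cohort") +
    ggplot2::theme_minimal()
}
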