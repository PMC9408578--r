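# ggplot2 displays for the result types.

#' @exportS3Method ggplot2::autoplot
autoplot.ecg_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::annotate(
      "point",
      x = 1 - object$spec_at_cutoff, y = object$sens_at_cutoff,
      shape = 4, size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f; Youden cutoff %g", object$auc,
                      object$youden_cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Plot ST-elevation pattern counts by culprit group
#'
#' @param cohort A cohort tibble (classified or not).
#' @param pattern `"main_pattern"` or `"fine_pattern"`.
#' @return A ggplot object.
#' @export
plot_pattern_counts <- function(cohort, pattern = c("main_pattern", "fine_pattern")) {
  pattern <- match.arg(pattern)
  if (!pattern %in% names(cohort)) cohort <- classify_cohort(cohort)
  ggplot2::ggplot(cohort, ggplot2::aes(y = .data[[pattern]])) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Patients", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot diagnostic operating points of evaluated criteria
#'
#' Sensitivity/specificity of each criterion in ROC space, with Wilson
#' interval bars on sensitivity.
#'
#' @param evaluation Output of [evaluate_criteria()].
#' @return A ggplot object.
#' @export
plot_criteria <- function(evaluation) {
  ggplot2::ggplot(
    evaluation,
    ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity,
                 label = .data$criterion)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sensitivity_low,
                                        ymax = .data$sensitivity_high),
                           width = 0.01) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}
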