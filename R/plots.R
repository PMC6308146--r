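#' Plot methods for result objects
#'
#' `autoplot.selection_report()` shows the AUC (with 95 percent CI) of each
#' significant feature; `autoplot.pca_reduction()` the per-component and
#' cumulative explained variance with the retention threshold;
#' `autoplot.cv_report()` the evaluation metrics per model.
#'
#' @param object the fitted object.
#' @param ... unused.
#' @return A ggplot object.
#' @name radrecur-autoplot
NULL

#' @rdname radrecur-autoplot
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, ...) {
  if (!nrow(object$roc)) stop("no significant features to plot")
  df <- dplyr::arrange(object$roc, .data$auc)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$feature)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "AUC (95% CI)", y = NULL,
                  title = "Discriminative significant features") +
    ggplot2::theme_minimal()
}

#' @rdname radrecur-autoplot
#' @method autoplot pca_reduction
#' @export
autoplot.pca_reduction <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$var_fraction,
                                   fill = .data$retained)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_var_fraction)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cum_var_fraction)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "Principal component", y = "Explained variance",
                  fill = "Retained") +
    ggplot2::theme_minimal()
}

#' @rdname radrecur-autoplot
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$metrics,
                            cols = c("tp_rate", "fp_rate", "precision",
                                     "f_measure", "mcc", "accuracy"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Value", fill = "Model",
                  title = "Cross-validated classification metrics") +
    ggplot2::theme_minimal()
}
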