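# ggplot2 visualizations for the main result types.

#' Plot a ROC curve
#'
#' @param object An `nc_roc`.
#' @param ... Unused.
#' @return A ggplot: sensitivity vs 1 - specificity with the chance diagonal
#'   and the AUC in the subtitle.
#' @exportS3Method ggplot2::autoplot
autoplot.nc_roc <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "1 - specificity (false positive rate)",
      y = "Sensitivity (true positive rate)",
      title = "ROC curve",
      subtitle = sprintf("AUC = %.4f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation accuracy surface
#'
#' @param object An `nc_cv_grid`.
#' @param ... Unused.
#' @return A ggplot: CVA as a tile map over the (alpha, lambda) grid, with
#'   the winning pair marked.
#' @exportS3Method ggplot2::autoplot
autoplot.nc_cv_grid <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = log10(.data$lambda),
                                            y = factor(.data$alpha),
                                            fill = .data$cva)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = log10(object$best_lambda),
                      y = as.character(object$best_alpha),
                      shape = 4, size = 3, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "CVA") +
    ggplot2::labs(
      x = "log10(lambda)", y = "alpha",
      title = "Cross-validated accuracy over the (alpha, lambda) grid",
      subtitle = sprintf("best: alpha=%g, lambda=%.4g, CVA=%.4f",
                         object$best_alpha, object$best_lambda, object$best_cva)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the selected-feature weights of a trained classifier
#'
#' @param model An `nc_classifier`.
#' @param top_n Show at most this many features by |weight| (default 25).
#' @return A ggplot bar chart of elastic-net weights (normalized scale).
#' @export
plot_feature_weights <- function(model, top_n = 25L) {
  td <- tidy(model)
  td <- td[order(-abs(td$enet_weight)), ]
  td <- utils::head(td, top_n)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$enet_weight, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Elastic-net weight (normalized feature scale)", y = NULL,
      title = "Selected feature signature"
    ) +
    ggplot2::theme_minimal()
}
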