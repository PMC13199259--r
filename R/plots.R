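#' @importFrom ggplot2 autoplot
NULL

#' Plot training history curves
#'
#' Per-epoch training/validation loss and validation metrics, with the best
#' (early-stopping) epoch marked.
#'
#' @param object A `"tabm_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tabm_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training history (dashed: best validation epoch)") +
    ggplot2::theme_minimal()
}

#' Plot a confusion-matrix heatmap
#'
#' @param object A `"metrics_report"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  cm <- object$confusion
  df <- tidyr::expand_grid(truth = object$per_class$class,
                           predicted = object$per_class$class)
  df$count <- as.vector(t(cm))
  df$truth <- factor(df$truth, levels = rev(object$per_class$class))
  df$predicted <- factor(df$predicted, levels = object$per_class$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "truth",
                  title = sprintf("Accuracy %.4f, macro F1 %.4f",
                                  object$accuracy, object$macro_f1)) +
    ggplot2::theme_minimal()
}

#' Plot top features by mean absolute attribution
#'
#' @param object An `"attribution_result"`.
#' @param class_index 0-based class to rank.
#' @param top_n Number of features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attribution_result <- function(object, class_index = 0, top_n = 10,
                                        ...) {
  rk <- feature_ranking(object, class_index = class_index)
  rk <- rk[seq_len(min(top_n, nrow(rk))), ]
  rk$feature <- factor(rk$feature, levels = rev(rk$feature))
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$mean_abs_attribution,
                                   y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |attribution|", y = NULL,
                  title = sprintf("Top features, class %d", class_index)) +
    ggplot2::theme_minimal()
}

#' Dependence scatter of two interacting features
#'
#' Attribution of feature `a` against its value, coloured by feature `b`'s
#' value — the plot that reveals how two indicators jointly move a class
#' prediction.
#'
#' @inheritParams interaction_table
#' @return A ggplot object.
#' @export
plot_interaction <- function(result, feature_a, feature_b, class_index = 0,
                             inputs) {
  df <- interaction_table(result, feature_a, feature_b,
                          class_index = class_index, inputs = inputs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value_a, y = .data$attribution_a,
                                   colour = .data$value_b)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   name = feature_b) +
    ggplot2::labs(x = feature_a, y = paste("attribution of", feature_a),
                  title = sprintf("Interaction %s x %s, class %d",
                                  feature_a, feature_b, class_index)) +
    ggplot2::theme_minimal()
}
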