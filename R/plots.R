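#' Boxplots of ReliefF weights per feature
#'
#' One box per feature over participants, with the zero line that
#' separates selected from discarded features under the median-positive
#' rule.
#'
#' @param weights Long tibble with `feature` and `weight` columns (e.g.
#'   the `weights` element of an `affect_study`).
#' @return A ggplot object.
#' @export
plot_feature_weights <- function(weights) {
  weights$feature <- factor(weights$feature, levels = feature_names())
  ggplot2::ggplot(weights,
                  ggplot2::aes(x = .data$feature, y = .data$weight)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6,
                          outlier.size = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ReliefF weight") +
    ggplot2::theme_minimal()
}

#' @method autoplot relieff_stability
#' @export
autoplot.relieff_stability <- function(object, ...) {
  object$feature <- factor(object$feature, levels = feature_names())
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$feature, y = .data$weight,
                               colour = factor(.data$k))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ReliefF weight", colour = "k") +
    ggplot2::theme_minimal()
}

#' @method autoplot optimal_feature_set
#' @export
autoplot.optimal_feature_set <- function(object, ...) {
  d <- object$medians
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature,
                                  y = .data$median_weight,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "median ReliefF weight",
                  fill = "selected") +
    ggplot2::theme_minimal()
}

#' @method autoplot affect_study
#' @export
autoplot.affect_study <- function(object, ...) {
  gl <- glance(object)
  ggplot2::ggplot(gl, ggplot2::aes(x = .data$algorithm,
                                   y = .data$mean_accuracy,
                                   fill = .data$feature_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~problem) +
    ggplot2::labs(x = NULL, y = "mean accuracy", fill = "feature set") +
    ggplot2::theme_minimal()
}
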