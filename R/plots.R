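# ggplot2 views of the main result types. Thin layers over the tidy
# tables; all styling left to the caller.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `tcem_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tcem_roc
#' @export
autoplot.tcem_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      subtitle = sprintf("AUC = %.3f", object$auc)
    )
}

#' Plot immunogenicity probability against expression percentile
#'
#' Lowess curve of the immunogenic indicator over the expression
#' percentile rank, the view in which the bimodal expression effect shows
#' up as an interior maximum.
#'
#' @param data Tibble with `expression_pct` and `immunogenic` (logical)
#'   columns.
#' @param span,iter Passed to [lowess_curve()].
#' @return A ggplot.
#' @export
plot_expression_immunogenicity <- function(data, span = 2 / 3, iter = 3L) {
  curve <- lowess_curve(data$expression_pct, data$immunogenic,
    span = span, iter = iter)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$fitted)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "cTEC expression (percentile rank)",
      y = "P(immunogenic)"
    )
}

#' Plot immunogenic:nonimmunogenic ratio across similarity bins
#'
#' @param bins Result of [similarity_bins()].
#' @return A ggplot.
#' @export
plot_similarity_bins <- function(bins) {
  p <- ggplot2::ggplot(
    bins$bins[!is.na(bins$bins$ratio), ],
    ggplot2::aes(x = .data$mean_similarity, y = .data$ratio)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Mean best-hit similarity",
      y = "Immunogenic : nonimmunogenic ratio"
    )
  if (!is.null(bins$spline)) {
    p <- p + ggplot2::geom_line(
      data = bins$spline,
      ggplot2::aes(x = .data$mean_similarity, y = .data$fitted)
    )
  }
  p
}

#' Heatmap of presented np-TCEM fractions by allele and species
#'
#' @param fractions Tibble with `species`, `allele`, `np_fraction`.
#' @return A ggplot.
#' @export
plot_np_heatmap <- function(fractions) {
  ggplot2::ggplot(
    fractions,
    ggplot2::aes(x = .data$species, y = .data$allele, fill = .data$np_fraction)
  ) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "np-TCEM\nfraction") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
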