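#' Plot an occupancy heatmap ordered by a consensus solution
#'
#' Draws the signal matrix as a tile heatmap with rows and columns ordered by
#' [order_heatmap()], cluster boundaries as separator lines -- the standard
#' way these occupancy matrices are displayed.
#'
#' @param object A `consensus_solution`.
#' @param X The [signal_matrix()] it was computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_solution <- function(object, X, ...) {
  lay <- order_heatmap(X, object)
  X0 <- unclass(as.matrix(X))
  d <- tibble(
    col = rep(seq_along(lay$col_order), each = length(lay$row_order)),
    row = rep(seq_along(lay$row_order), times = length(lay$col_order)),
    signal = as.numeric(X0[lay$row_order, lay$col_order])
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_vline(xintercept = lay$col_boundaries + 0.5,
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = lay$row_boundaries + 0.5,
                        linewidth = 0.3) +
    ggplot2::labs(x = "promoters (heatmap order)",
                  y = "experiments (heatmap order)", fill = "signal") +
    ggplot2::theme_minimal()
}

#' Bar panel of row-cluster association significance
#'
#' One bar per retained row and column cluster, extending to
#' `-log10(p)` of the Welch t-test of the row inside vs outside the cluster
#' -- the annotation drawn beside the ordered heatmap.
#'
#' @param consensus A `consensus_solution` with computed `row_tests`.
#' @return A ggplot object.
#' @export
plot_row_association <- function(consensus) {
  d <- consensus$row_tests
  ggplot2::ggplot(d, ggplot2::aes(.data$neglog10p,
                                  stats::reorder(.data$row_id, .data$neglog10p))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of quadruple-scan correlations
#'
#' @param object A `quadruple_scan`.
#' @param fraction Good-set threshold to mark (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quadruple_scan <- function(object, fraction = 0.95, ...) {
  ggplot2::ggplot(object$subsets, ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(xintercept = fraction * object$r_full,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$r_full) +
    ggplot2::labs(x = "Pearson r (subset model)", y = "subsets") +
    ggplot2::theme_minimal()
}
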