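#' Scatter plot of differential island calls
#'
#' Wild-type versus mutant pair-normalized tag counts on log2 axes,
#' coloured by differential label, with the fold-change threshold drawn
#' as guide lines.
#'
#' @param calls Output of [call_differential()] with `wt`, `mut`, `label`
#'   columns.
#' @param threshold Threshold used for the guide lines.
#' @return A ggplot object.
#' @export
plot_differential <- function(calls, threshold = 1.8) {
  stopifnot(all(c("wt", "mut", "label") %in% names(calls)))
  ggplot2::ggplot(calls, ggplot2::aes(x = log2(.data$wt + 1),
                                      y = log2(.data$mut + 1),
                                      colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = log2(threshold),
                         linetype = 3, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = -log2(threshold),
                         linetype = 3, colour = "grey60") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(decreased = "#c23b22",
                                            increased = "#2e7d32",
                                            unchanged = "grey50")) +
    ggplot2::labs(x = "log2 WT tags + 1", y = "log2 mutant tags + 1",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname motif_enrichment
#' @param object A `motif_enrichment` object.
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  df <- tibble(
    what = factor(c("observed", "permutation null"),
                  levels = c("observed", "permutation null")),
    mean_per_window = c(object$observed_mean, object$null_mean)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$mean_per_window)) +
    ggplot2::geom_col(width = 0.6, fill = c("#4a6fa5", "grey60")) +
    ggplot2::labs(x = NULL,
                  y = sprintf("mean %s motifs per %d bp window",
                              paste(object$motifs[1:2], collapse = "/"),
                              2 * object$window_bp + 1),
                  subtitle = sprintf("chi-squared = %.2f, p = %.2g",
                                     object$chi2_statistic, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @rdname venn_partition
#' @param object A `venn_partition` object.
#' @param ... Unused.
#' @export
autoplot.venn_partition <- function(object, ...) {
  df <- object$counts
  df$cell <- factor(df$cell, levels = df$cell)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$n)) +
    ggplot2::geom_col(fill = "#4a6fa5") +
    ggplot2::labs(x = "co-localization cell", y = "merged regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname kmeans_cluster
#' @param object An `island_kmeans` object.
#' @export
autoplot.island_kmeans <- function(object, ...) {
  m <- object$matrix[order(object$cluster), , drop = FALSE]
  df <- tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    column = rep(colnames(m) %||% paste0("V", seq_len(ncol(m))),
                 each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "regions (grouped by cluster)",
                  fill = "z") +
    ggplot2::theme_minimal()
}
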