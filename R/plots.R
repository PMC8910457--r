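#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gene-vs-PAL correlation comparison
#'
#' Paired box plot of the per-sample correlation distributions at the
#' gene and PAL levels, the standard visual for the aggregation-gain
#' comparison; when the sets are paired, light segments join the two
#' values of each sample.
#'
#' @param object A `level_comparison` from [compare_levels()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.level_comparison <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$level,
                                        y = .data$correlation,
                                        fill = .data$level))
  if (!is.null(object$ids)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$id),
                                colour = "grey70", linewidth = 0.2)
  }
  p +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    ggplot2::scale_x_discrete(labels = c(gene = "gene level",
                                         pal = "PAL level")) +
    ggplot2::labs(x = NULL, y = "RNA–protein correlation",
                  subtitle = sprintf(
                    "fold change %.2f, Wilcoxon p = %.2g",
                    object$fold_change, object$p_value)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot a correlation set
#'
#' Histogram of the per-sample or per-feature correlation values.
#'
#' @param object A `correlation_set`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_set <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$correlation)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = mean(object$correlation),
                        linetype = 2) +
    ggplot2::labs(x = sprintf("%s correlation (%s, %s level)",
                              attr(object, "method"), attr(object, "axis"),
                              attr(object, "level")),
                  y = "count") +
    ggplot2::theme_minimal()
}

#' Heatmap of a PAL matrix
#'
#' Pathways-by-samples tile plot of activation levels, diverging around
#' zero (positive = up-regulated). With many pathways only the
#' `max_pathways` most variable rows are shown.
#'
#' @param object A `pal_tbl` from [pal_matrix()].
#' @param max_pathways Row cap (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pal_tbl <- function(object, max_pathways = 40, ...) {
  m <- pal_values(object)
  if (nrow(m) > max_pathways) {
    keep <- order(-apply(m, 1, stats::var))[seq_len(max_pathways)]
    m <- m[keep, , drop = FALSE]
  }
  df <- tibble::as_tibble(m, rownames = "pathway_id") |>
    tidyr::pivot_longer(-"pathway_id", names_to = "sample",
                        values_to = "pal")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$pathway_id,
                                   fill = .data$pal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "PAL") +
    ggplot2::labs(x = "sample", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot the most/least-correlated pathway tables
#'
#' Horizontal bar chart of the `rank_pathways()` output.
#'
#' @param rankings The tibble returned by [rank_pathways()].
#' @return A ggplot object.
#' @export
plot_rank_pathways <- function(rankings) {
  df <- dplyr::mutate(rankings,
                      pathway_id = stats::reorder(.data$pathway_id,
                                                  .data$spearman))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spearman, y = .data$pathway_id,
                                   fill = .data$table)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~table, scales = "free_y") +
    ggplot2::labs(x = "Spearman correlation", y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
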