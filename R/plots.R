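#' Degree distribution on log-log axes
#'
#' The standard scale-free diagnostic: node count per degree, both axes on
#' log scale, where a power-law decay appears as a straight line.
#'
#' @param g An igraph interactome.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(g) {
  degree_histogram(g) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$degree, y = .data$n_nodes)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "number of nodes",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_degree_distribution Null LCC-size distribution with the
#'   observed value marked.
#' @param object An axonmod result object.
#' @param ... Unused.
#' @export
autoplot.lcc_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$null_lcc_size)) +
    ggplot2::geom_bar(fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_size,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "LCC size of random sets", y = "count",
      title = sprintf("LCC of '%s': observed %d, z = %.2f, p = %.3g",
                      object$seed_name, object$observed_size,
                      object$z_score, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_degree_distribution Null separation-score distribution
#'   with the observed `s_AB` marked.
#' @export
autoplot.separation_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$null_s_AB)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$s_AB,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "s_AB of random set pairs", y = "count",
      title = sprintf("%s vs %s: s_AB = %.3f (%s)", object$name_a,
                      object$name_b, object$s_AB, object$classification)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_degree_distribution Connectivity p-value along the
#'   DIAMOnD incorporation sequence.
#' @export
autoplot.diamond_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$iteration, y = .data$p_value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$seed_links), alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "connectivity p-value",
                  size = "links into module",
                  title = sprintf("DIAMOnD expansion of '%s'",
                                  object$module$seed_name)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_degree_distribution Observed nearest-seed distance
#'   distribution.
#' @export
autoplot.proximity_result <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$reachable) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_bar(fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$mean_ds, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "hop distance to nearest other seed", y = "seeds",
                  title = sprintf("Seed shortest distances (mean %.2f)",
                                  object$mean_ds)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a semantic-similarity matrix
#'
#' @param mat A matrix from [semsim_matrix()].
#' @param order_by_cluster Reorder rows/columns by hierarchical clustering
#'   (square matrices only).
#' @return A ggplot object.
#' @export
plot_semsim <- function(mat, order_by_cluster = TRUE) {
  if (order_by_cluster && nrow(mat) == ncol(mat) &&
      all(rownames(mat) == colnames(mat))) {
    ord <- cluster_semsim(mat)$hclust$order
    mat <- mat[ord, ord]
  }
  tibble::as_tibble(mat, rownames = "gene_a") |>
    tidyr::pivot_longer(-"gene_a", names_to = "gene_b", values_to = "similarity") |>
    dplyr::mutate(gene_a = factor(.data$gene_a, levels = rownames(mat)),
                  gene_b = factor(.data$gene_b, levels = colnames(mat))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$gene_b, y = .data$gene_a,
                                 fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Wang BMA") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Bar chart of enrichment results
#'
#' @param rows A tibble from [ora()] (typically after [filter_fdr()]).
#' @param top_n Number of pathways to show, ranked by FDR.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(rows, top_n = 20) {
  rows |>
    dplyr::arrange(.data$fdr) |>
    head(top_n) |>
    dplyr::mutate(pathway = stats::reorder(.data$pathway, -.data$fdr)) |>
    ggplot2::ggplot(ggplot2::aes(x = -log10(.data$fdr), y = .data$pathway,
                                 fill = .data$enrichment_ratio)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ FDR), y = NULL,
                  fill = "enrichment\nratio") +
    ggplot2::theme_minimal()
}
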