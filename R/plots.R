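#' Heatmap of a pairwise comparison matrix
#'
#' Tile heatmap of a `phamnet_matrix`, rows and columns ordered by
#' [order_heatmap()] (maximum-metric distances, single-linkage) so
#' related phages form contiguous blocks.
#'
#' @param object A `phamnet_matrix` from [all_pairs()].
#' @param order Reorder rows/columns by the dendrogram leaf order
#'   (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phamnet_matrix <- function(object, order = TRUE, ...) {
  vals <- object$values
  if (order) {
    ord <- order_heatmap(object)
    vals <- vals[ord, ord]
  }
  ids <- rownames(vals)
  df <- tidyr::expand_grid(phage_a = ids, phage_b = ids)
  df$value <- vals[cbind(df$phage_a, df$phage_b)]
  df$phage_a <- factor(df$phage_a, levels = ids)
  df$phage_b <- factor(df$phage_b, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(.data$phage_a, .data$phage_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = toupper(object$metric)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}

#' Genomic similarity plot (gene-content dissimilarity vs nucleotide
#' distance)
#'
#' Scatter of per-pair gene-content dissimilarity against nucleotide
#' distance, with the network edge thresholds drawn as dashed lines:
#' pairs inside the lower-left box are the "intra-cluster" comparisons
#' retained as network edges.
#'
#' @param pairs Long table from [similarity_table()] (columns `gcd`,
#'   `nucleotide_distance`).
#' @param config A [taxonomy_config()] providing the thresholds.
#' @return A ggplot object.
#' @export
plot_gcd_nd <- function(pairs, config = taxonomy_config()) {
  ggplot2::ggplot(pairs, ggplot2::aes(.data$nucleotide_distance,
                                      .data$gcd)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = config$network_gcd_max,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = config$network_nd_max,
                        linetype = "dashed") +
    ggplot2::labs(x = "nucleotide distance",
                  y = "gene content dissimilarity") +
    ggplot2::theme_minimal()
}

#' Genome network plot
#'
#' Nodes are phages, edges the retained intra-cluster pairs; layout by
#' Fruchterman-Reingold (deterministic under a set seed). Edge length
#' carries no biological meaning.
#'
#' @param object A `genome_network` from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genome_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[c("phage_a", "phage_b")], directed = FALSE,
    vertices = object$components$phage_id)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(phage_id = igraph::V(g)$name,
                  x = xy[, 1], y = xy[, 2])
  nodes <- left_join(nodes, object$components, by = "phage_id")
  seg <- left_join(object$edges, nodes, by = c(phage_a = "phage_id")) |>
    left_join(nodes, by = c(phage_b = "phage_id"),
              suffix = c("", "_b"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_b,
                                       yend = .data$y_b),
                          color = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y,
                                     color = factor(.data$component)),
                        size = 3) +
    ggplot2::labs(color = "component") +
    ggplot2::theme_void()
}

#' Motif map along a genome
#'
#' Positions of motif hits along the genome with gene intervals as a
#' rug, a quick visual check of intergenic placement and spacing.
#'
#' @param genome A [phage_genome()].
#' @param hits Hit tibble from [scan_motif()] or
#'   [find_inverted_repeats()].
#' @return A ggplot object.
#' @export
plot_motif_map <- function(genome, hits) {
  genes <- genome$genes
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = genes,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 0.4),
                       fill = "grey80") +
    ggplot2::geom_segment(data = hits,
                          ggplot2::aes(x = .data$start,
                                       xend = .data$start,
                                       y = 0.5, yend = 1,
                                       color = .data$strand)) +
    ggplot2::scale_y_continuous(limits = c(0, 1.2), breaks = NULL) +
    ggplot2::labs(x = sprintf("%s position (bp)", genome$phage_id),
                  y = NULL) +
    ggplot2::theme_minimal()
}
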