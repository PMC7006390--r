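#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

plot_document <- function(doc, title = NULL) {
  pos <- document_layout(doc)
  nodes <- dplyr::left_join(doc$nodes, pos, by = "id")
  edges <- doc$edges |>
    dplyr::left_join(pos, by = c("from" = "id")) |>
    dplyr::left_join(pos, by = c("to" = "id"), suffix = c("", "_to"))
  fill_values <- doc$palette[unique(nodes$color_key)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to),
      color = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$color_key,
                   shape = .data$kind),
      size = 3, color = "grey30"
    ) +
    ggplot2::scale_shape_manual(values = c(gene = 21, pathway = 23)) +
    ggplot2::scale_fill_manual(values = fill_values) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title, fill = "color", shape = "node")
  p
}

#' Plot a leveled gene/pathway network
#'
#' Static ggplot2 rendering of the network with the same node shapes and
#' colors as the interactive HTML export: gene circles (green), pathway
#' diamonds colored by level, orange for pathways with no attached gene.
#'
#' @param object A [build_network()] result.
#' @param layout_seed Seed fixing node positions.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot leveled_network
#' @export
autoplot.leveled_network <- function(object, layout_seed = 42L, ...) {
  plot_document(to_document(object, layout_seed = layout_seed),
                title = "Leveled pathway network")
}

#' Plot a DEG-to-pathway expression network
#'
#' @param object A [build_expression_network()] result.
#' @param layout_seed Seed fixing node positions.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot expression_network
#' @export
autoplot.expression_network <- function(object, layout_seed = 42L, ...) {
  plot_document(to_document(object, layout_seed = layout_seed),
                title = "Expression network")
}

#' Bar chart of an enrichment result
#'
#' Shows the top pathways by over-representation p-value on a -log10 scale.
#'
#' @param object An [enrich_global()] / [enrich_network()] result.
#' @param top Number of pathways to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top = 15L, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$pathway <- factor(df$pathway_id, levels = rev(df$pathway_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$pathway)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  title = "Pathway over-representation") +
    ggplot2::theme_minimal()
}
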