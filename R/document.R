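# Node color scheme, following the legend conventions of the original tool:
# candidate genes are green circles; pathway diamonds are colored by level
# (violet 1L, yellow 2L, blue 3L, then a fixed 8-color cycle), orange when no
# candidate gene connects to them; expression networks use a light-to-dark
# red scale for upregulated nodes and a green scale for downregulated ones.

level_palette_base <- c("violet", "yellow", "blue")
level_palette_extended <- c("pink", "brown", "cyan", "magenta",
                            "gray", "olive", "navy", "coral")

level_color_key <- function(level) {
  vapply(as.integer(level), function(l) {
    stopifnot(l >= 1)
    name <- if (l <= 3) {
      level_palette_base[l]
    } else {
      level_palette_extended[((l - 4L) %% length(level_palette_extended)) + 1L]
    }
    sprintf("%s_%dL", name, l)
  }, character(1))
}

bin_color_key <- function(direction, magnitude) {
  scale <- ifelse(direction == "up", "red", "green")
  paste0(scale, "_", as.character(magnitude))
}

#' Default node color palette
#'
#' Maps every color key a [to_document()] call can emit to a CSS color.
#' Level keys beyond the depth requested are generated on demand by
#' [to_document()]; this function returns the palette for a given maximum
#' level.
#'
#' @param max_level Deepest pathway level to include keys for.
#' @return Named character vector: color key -> CSS color.
#' @export
default_palette <- function(max_level = 10L) {
  lv <- stats::setNames(
    c("mediumpurple", "gold", "steelblue",
      rep_len(level_palette_extended, max(0L, max_level - 3L)))[seq_len(max_level)],
    level_color_key(seq_len(max_level))
  )
  c(
    lv,
    orange_unconnected = "orange",
    green_gene = "mediumseagreen",
    red_low = "mistyrose", red_moderate = "lightcoral",
    red_high = "red", red_strong = "darkred",
    green_low = "honeydew", green_moderate = "lightgreen",
    green_high = "green", green_strong = "darkgreen"
  )
}

new_network_document <- function(nodes, edges, layout_seed, palette) {
  if (anyDuplicated(nodes$id)) {
    rlang::abort("network document node ids must be unique",
                 class = c("pathlevels_internal_error", "pathlevels_error"))
  }
  dangling <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(dangling) > 0) {
    rlang::abort(sprintf("edge references unknown node(s): %s",
                         paste(utils::head(dangling, 5), collapse = ", ")),
                 class = c("pathlevels_internal_error", "pathlevels_error"))
  }
  unknown_key <- setdiff(nodes$color_key, names(palette))
  if (length(unknown_key) > 0) {
    rlang::abort(sprintf("color key(s) missing from palette: %s",
                         paste(unknown_key, collapse = ", ")),
                 class = c("pathlevels_internal_error", "pathlevels_error"))
  }
  structure(
    list(nodes = nodes, edges = edges,
         layout_seed = as.integer(layout_seed), palette = palette),
    class = "network_document"
  )
}

#' Convert a network into a drawable document
#'
#' Normalizes a leveled gene/pathway network or an expression network into a
#' flat node/edge document for rendering: genes become circles, pathways
#' diamonds. In leveled networks pathways are colored by level (violet 1L,
#' yellow 2L, blue 3L, deeper levels from a fixed cycle) and pathways
#' without any attached candidate gene are orange; candidate genes are
#' green. In expression networks nodes are colored by their regulation bin
#' on a red (up) or green (down) scale, light to dark with magnitude.
#'
#' @param network A [build_network()] or [build_expression_network()] result.
#' @param palette Named color map; defaults to [default_palette()].
#' @param layout_seed Integer seed fixing node positions in
#'   [render_html()] and [autoplot()] layouts.
#' @return An object of class `network_document`: list with `nodes` (tibble
#'   `id`, `label`, `kind`, `shape`, `color_key`, `level`, `bin`), `edges`
#'   (tibble `from`, `to`), `layout_seed`, `palette`.
#' @export
to_document <- function(network, palette = NULL, layout_seed = 42L) {
  UseMethod("to_document")
}

#' @export
to_document.leveled_network <- function(network, palette = NULL, layout_seed = 42L) {
  max_level <- max(network$assignment$level, 3L)
  palette <- palette %||% default_palette(max_level)
  connected <- unique(network$attachments$pathway_id)
  pw <- network$assignment |>
    dplyr::left_join(
      dplyr::distinct(network$attachments[c("pathway_id", "pathway_title")]),
      by = "pathway_id"
    )
  pathway_nodes <- tibble::tibble(
    id = pw$pathway_id,
    label = pw$pathway_id,
    kind = "pathway",
    shape = "diamond",
    color_key = ifelse(pw$pathway_id %in% connected,
                       level_color_key(pw$level), "orange_unconnected"),
    level = pw$level,
    bin = NA_character_
  )
  genes <- dplyr::distinct(network$attachments[c("gene_id", "external_id")])
  gene_nodes <- tibble::tibble(
    id = genes$gene_id,
    label = genes$external_id,
    kind = "gene",
    shape = "circle",
    color_key = "green_gene",
    level = NA_integer_,
    bin = NA_character_
  )
  edges <- dplyr::bind_rows(
    network$pathway_edges,
    tibble::tibble(from = network$attachments$gene_id,
                   to = network$attachments$pathway_id)
  )
  edges <- dplyr::distinct(dplyr::arrange(edges, .data$from, .data$to))
  new_network_document(dplyr::bind_rows(pathway_nodes, gene_nodes),
                       edges, layout_seed, palette)
}

#' @export
to_document.expression_network <- function(network, palette = NULL, layout_seed = 42L) {
  palette <- palette %||% default_palette()
  gene_nodes <- tibble::tibble(
    id = network$gene_nodes$gene_id,
    label = network$gene_nodes$external_id,
    kind = "gene",
    shape = "circle",
    color_key = bin_color_key(network$gene_nodes$direction,
                              network$gene_nodes$magnitude),
    level = NA_integer_,
    bin = paste0(network$gene_nodes$direction, "_",
                 as.character(network$gene_nodes$magnitude))
  )
  pathway_nodes <- tibble::tibble(
    id = network$pathway_nodes$pathway_id,
    label = network$pathway_nodes$pathway_id,
    kind = "pathway",
    shape = "diamond",
    color_key = bin_color_key(network$pathway_nodes$direction,
                              network$pathway_nodes$magnitude),
    level = NA_integer_,
    bin = paste0(network$pathway_nodes$direction, "_",
                 as.character(network$pathway_nodes$magnitude))
  )
  edges <- dplyr::arrange(
    tibble::tibble(from = network$edges$gene_id, to = network$edges$pathway_id),
    .data$from, .data$to
  )
  new_network_document(dplyr::bind_rows(pathway_nodes, gene_nodes),
                       edges, layout_seed, palette)
}

#' @export
print.network_document <- function(x, ...) {
  cat(sprintf("<network_document> %d nodes, %d edges, layout seed %d\n",
              nrow(x$nodes), nrow(x$edges), x$layout_seed))
  invisible(x)
}

# deterministic seeded force-directed positions; 0- and 1-node cases handled
document_layout <- function(doc) {
  n <- nrow(doc$nodes)
  if (n == 0) {
    return(tibble::tibble(id = character(), x = numeric(), y = numeric()))
  }
  g <- igraph::graph_from_data_frame(
    doc$edges, directed = FALSE,
    vertices = doc$nodes["id"]
  )
  xy <- withr::with_seed(doc$layout_seed, igraph::layout_with_fr(g))
  xy <- round(xy, 4)
  tibble::tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}
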