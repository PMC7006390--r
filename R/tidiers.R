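#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a leveled network into its attachment table
#'
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @return Tibble of gene-to-pathway attachments (`gene_id`, `external_id`,
#'   `pathway_id`, `pathway_title`, `level`).
#' @method tidy leveled_network
#' @export
tidy.leveled_network <- function(x, ...) {
  tibble::as_tibble(x$attachments)
}

#' One-row summary of a leveled network
#'
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @return Tibble with `n_pathways`, `n_levels`, `n_pathway_links`,
#'   `n_candidates`, `n_highlighted` (unique genes with at least one
#'   attachment), `n_attachments`.
#' @method glance leveled_network
#' @export
glance.leveled_network <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x$assignment),
    n_levels = attr(x$assignment, "n_levels"),
    n_pathway_links = nrow(x$pathway_edges),
    n_candidates = nrow(x$genes),
    n_highlighted = length(unique(x$attachments$gene_id)),
    n_attachments = nrow(x$attachments)
  )
}

#' Tidy an expression network into a node table
#'
#' @param x A [build_expression_network()] result.
#' @param ... Unused.
#' @return Tibble with one row per node: `id`, `label`, `kind`, `value`
#'   (fold change or pathway score), `direction`, `magnitude`, `n_edges`.
#' @method tidy expression_network
#' @export
tidy.expression_network <- function(x, ...) {
  deg <- dplyr::count(x$edges, .data$gene_id, name = "n_edges")
  pwd <- dplyr::count(x$edges, .data$pathway_id, name = "n_edges")
  dplyr::bind_rows(
    x$gene_nodes |>
      dplyr::left_join(deg, by = "gene_id") |>
      dplyr::transmute(id = .data$gene_id, label = .data$external_id,
                       kind = "gene", value = .data$fold_change,
                       direction = .data$direction,
                       magnitude = as.character(.data$magnitude),
                       n_edges = dplyr::coalesce(.data$n_edges, 0L)),
    x$pathway_nodes |>
      dplyr::left_join(pwd, by = "pathway_id") |>
      dplyr::transmute(id = .data$pathway_id, label = .data$title,
                       kind = "pathway", value = .data$score,
                       direction = .data$direction,
                       magnitude = as.character(.data$magnitude),
                       n_edges = dplyr::coalesce(.data$n_edges, 0L))
  )
}

#' One-row summary of an expression network
#'
#' @param x A [build_expression_network()] result.
#' @param ... Unused.
#' @return Tibble with node/edge counts and the counts of up- and
#'   downregulated gene nodes.
#' @method glance expression_network
#' @export
glance.expression_network <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$gene_nodes),
    n_pathways = nrow(x$pathway_nodes),
    n_edges = nrow(x$edges),
    n_up = sum(x$gene_nodes$direction == "up"),
    n_down = sum(x$gene_nodes$direction == "down"),
    n_isolated_genes = length(setdiff(x$gene_nodes$gene_id, x$edges$gene_id))
  )
}

#' Tidy an enrichment result
#'
#' @param x An [enrich_global()] / [enrich_network()] result.
#' @param ... Unused.
#' @return The underlying tibble (`pathway_id`, `title`, `k`, `K`, `n`,
#'   `N`, `p_value`, `p_adjusted`).
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an enrichment result
#'
#' @param x An [enrich_global()] / [enrich_network()] result.
#' @param alpha Significance threshold used for the `n_significant` count.
#' @param ... Unused.
#' @return Tibble with `n_pathways_tested`, `background_size`,
#'   `n_candidates_in_background`, `candidates_outside_background`,
#'   `min_p`, `n_significant`.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_pathways_tested = nrow(x),
    background_size = attr(x, "background_size"),
    n_candidates_in_background = if (nrow(x) > 0) x$n[1] else 0L,
    candidates_outside_background = attr(x, "candidates_outside_background"),
    min_p = if (nrow(x) > 0) min(x$p_value) else NA_real_,
    n_significant = sum(x$p_value <= alpha)
  )
}
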