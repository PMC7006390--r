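#' Filter a DEG table by p-value cutoff
#'
#' Retains rows with `p_value <= cutoff` (inclusive), preserving order.
#'
#' @param degs DEG tibble with columns `gene_id`, `fold_change`, `p_value`
#'   (as from [prepare_expression_list()]).
#' @param cutoff P-value cut-off in `(0, 1]`.
#' @return The filtered tibble.
#' @export
filter_degs <- function(degs, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff) ||
      cutoff <= 0 || cutoff > 1) {
    abort_input("cutoff must be a single value in (0, 1]")
  }
  degs <- tibble::as_tibble(degs)
  validate_deg_values(degs$fold_change, degs$p_value,
                      degs$external_id %||% degs$gene_id)
  degs[degs$p_value <= cutoff, ]
}

#' Classify signed expression values into regulation bins
#'
#' Each gene fold change or pathway expression score is expressed as a
#' fraction `r` of the top (maximum-magnitude) value of the same direction
#' within its node class, then binned: `low` for `r < 0.25`, `moderate` for
#' `0.25 <= r < 0.50`, `high` for `0.50 <= r < 0.75`, `strong` for
#' `r >= 0.75` (lower bounds inclusive). Direction follows the sign of the
#' value; upregulated nodes draw on a red scale, downregulated on a green
#' scale, light to dark with magnitude.
#'
#' @param values Numeric vector of signed, non-zero values.
#' @param top_up Maximum among positive values of the node class (required
#'   and `> 0` when any value is positive).
#' @param top_down Maximum magnitude among negative values of the node class
#'   (required and `> 0` when any value is negative).
#' @return Tibble with columns `direction` (`"up"`/`"down"`), `magnitude`
#'   (ordered factor `low < moderate < high < strong`) and `ratio` (`r`).
#' @export
#' @examples
#' classify_value(c(1, 4, -0.4), top_up = 4, top_down = 4)
classify_value <- function(values, top_up = NULL, top_down = NULL) {
  if (any(!is.finite(values))) abort_input("values must be finite")
  if (any(values == 0)) {
    abort_input("value 0 has no regulation direction; zero values are invalid")
  }
  if (any(values > 0)) {
    if (is.null(top_up) || !is.finite(top_up) || top_up <= 0) {
      rlang::abort("positive values present but top_up missing or not > 0",
                   class = c("pathlevels_internal_error", "pathlevels_error"))
    }
  }
  if (any(values < 0)) {
    if (is.null(top_down) || !is.finite(top_down) || top_down <= 0) {
      rlang::abort("negative values present but top_down missing or not > 0",
                   class = c("pathlevels_internal_error", "pathlevels_error"))
    }
  }
  r <- ifelse(values > 0, values / top_up, abs(values) / top_down)
  magnitude <- cut(r, breaks = c(0, 0.25, 0.50, 0.75, Inf),
                   labels = c("low", "moderate", "high", "strong"),
                   right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
  tibble::tibble(
    direction = ifelse(values > 0, "up", "down"),
    magnitude = magnitude,
    ratio = r
  )
}

# same-direction tops of a value vector; NULL when that direction is absent
direction_tops <- function(values) {
  list(
    up = if (any(values > 0)) max(values[values > 0]) else NULL,
    down = if (any(values < 0)) max(abs(values[values < 0])) else NULL
  )
}

#' Build the DEG-to-pathway expression network
#'
#' Connects a (filtered) DEG table to a user-supplied list of scored
#' pathways of interest: an edge joins gene `g` to pathway `p` when `g` is
#' annotated to `p`. No level expansion is performed — the pathway side is
#' exactly the scored list. Gene nodes are binned by fold change (tops taken
#' over the filtered DEG table) and pathway nodes by their expression
#' estimated score (tops over the score list); see [classify_value()].
#' DEGs annotated to none of the scored pathways remain as isolated nodes.
#'
#' @param degs Filtered DEG tibble (`gene_id`, `fold_change`, `p_value`).
#' @param scores Data frame with columns `pathway_id`, `score` (signed,
#'   non-zero, finite; unique pathway ids; at least one row).
#' @param universe A [pathway_universe()].
#' @return An object of class `expression_network`: list with `gene_nodes`
#'   (tibble `gene_id`, `external_id`, `fold_change`, `direction`,
#'   `magnitude`), `pathway_nodes` (tibble `pathway_id`, `title`, `score`,
#'   `direction`, `magnitude`), `edges` (tibble `gene_id`, `pathway_id`),
#'   and `organism`.
#' @export
build_expression_network <- function(degs, scores, universe) {
  assert_universe(universe)
  degs <- tibble::as_tibble(degs)
  scores <- tibble::as_tibble(scores)[c("pathway_id", "score")]
  if (nrow(scores) == 0) abort_input("pathway score list must have at least one row")
  scores$pathway_id <- normalize_pathway_ids(scores$pathway_id, universe$organism$code)
  if (anyDuplicated(scores$pathway_id)) abort_input("duplicated pathway ids in score list")
  missing <- setdiff(scores$pathway_id, universe$records$pathway_id)
  if (length(missing) > 0) {
    abort_input(sprintf("scored pathway(s) not in universe: %s",
                        paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(scores$score) | scores$score == 0)) {
    abort_input("pathway scores must be finite and non-zero")
  }
  if (nrow(degs) > 0) {
    validate_deg_values(degs$fold_change, degs$p_value,
                        degs$external_id %||% degs$gene_id)
  }

  gene_nodes <- if (nrow(degs) > 0) {
    tops <- direction_tops(degs$fold_change)
    dplyr::bind_cols(
      tibble::tibble(gene_id = as.character(degs$gene_id),
                     external_id = degs$external_id %||% as.character(degs$gene_id),
                     fold_change = degs$fold_change),
      classify_value(degs$fold_change, tops$up, tops$down)[c("direction", "magnitude")]
    )
  } else {
    tibble::tibble(gene_id = character(), external_id = character(),
                   fold_change = numeric(), direction = character(),
                   magnitude = factor(character(),
                                      levels = c("low", "moderate", "high", "strong"),
                                      ordered = TRUE))
  }

  ptops <- direction_tops(scores$score)
  pathway_nodes <- dplyr::bind_cols(
    dplyr::left_join(scores, universe$records, by = "pathway_id")[
      c("pathway_id", "title", "score")],
    classify_value(scores$score, ptops$up, ptops$down)[c("direction", "magnitude")]
  )

  edges <- universe$gene_map |>
    dplyr::filter(.data$gene_id %in% gene_nodes$gene_id,
                  .data$pathway_id %in% scores$pathway_id) |>
    dplyr::arrange(.data$gene_id, .data$pathway_id)

  isolated <- setdiff(gene_nodes$gene_id, edges$gene_id)
  if (length(isolated) > 0) {
    message(sprintf(
      "build_expression_network: %d DEG(s) connect to none of the scored pathways and stay isolated",
      length(isolated)
    ))
  }

  structure(
    list(gene_nodes = gene_nodes, pathway_nodes = pathway_nodes,
         edges = edges, organism = universe$organism),
    class = "expression_network"
  )
}

#' @export
print.expression_network <- function(x, ...) {
  cat(sprintf(
    "<expression_network> %d DEG node(s), %d scored pathway(s), %d gene-pathway edge(s)\n",
    nrow(x$gene_nodes), nrow(x$pathway_nodes), nrow(x$edges)
  ))
  invisible(x)
}
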