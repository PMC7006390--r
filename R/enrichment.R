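#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the over-representation
#' p-value of observing at least `k` candidate genes in a pathway holding
#' `K` of the `N` background genes when `n` candidates fall in the
#' background (the one-sided Fisher exact test). Computed through the
#' distribution's survival function, which is numerically stable for large
#' counts.
#'
#' @param k Observed overlap (candidates in the pathway).
#' @param K Background genes in the pathway.
#' @param n Candidate genes in the background.
#' @param N Background size.
#' @return Probability in `[0, 1]`. All arguments recycle.
#' @export
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10)  # 66/252
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  ints <- c(k, K, n, N)
  if (any(!is.finite(ints)) || any(ints < 0) || any(ints != as.integer(ints))) {
    abort_input("k, K, n, N must be non-negative integers")
  }
  if (any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    abort_input("need k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == len) x else rep_len(x, len)
  })
}

enrich_table <- function(candidates, gene_map, records, adjust) {
  background <- unique(gene_map$gene_id)
  N <- length(background)
  cand_in <- intersect(unique(candidates), background)
  n_out <- length(unique(candidates)) - length(cand_in)
  if (length(cand_in) == 0) {
    abort_input(paste(
      "no candidate gene overlaps the background;",
      "check that candidate ids are entrez-style and mapped through the annotation"
    ))
  }
  res <- gene_map |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      k = sum(unique(.data$gene_id) %in% cand_in),
      K = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = length(cand_in),
      N = N,
      p_value = hypergeom_upper_tail(.data$k, .data$K, .data$n, .data$N)
    ) |>
    dplyr::left_join(records, by = "pathway_id") |>
    dplyr::select("pathway_id", "title", "k", "K", "n", "N", "p_value") |>
    dplyr::arrange(.data$p_value, .data$pathway_id)
  res$p_adjusted <- if (identical(adjust, "benjamini_hochberg")) {
    stats::p.adjust(res$p_value, method = "BH")
  } else {
    NA_real_
  }
  structure(res,
            candidates_outside_background = n_out,
            background_size = N,
            class = c("enrichment_result", class(tibble::tibble())))
}

#' Hypergeometric over-representation against the global universe
#'
#' Tests every pathway with at least one annotated gene for
#' over-representation of the candidate genes, against the background of
#' all genes carrying at least one pathway annotation in the universe.
#' Candidates outside the background are excluded from `n` and counted in
#' the `candidates_outside_background` attribute.
#'
#' @param candidates Character vector of candidate gene ids (entrez-style).
#' @param universe A [pathway_universe()].
#' @param adjust `"none"` (raw p-values only) or `"benjamini_hochberg"`.
#' @return A tibble of class `enrichment_result` with columns `pathway_id`,
#'   `title`, `k`, `K`, `n`, `N`, `p_value`, `p_adjusted`, sorted by
#'   ascending `p_value` (ties by pathway id).
#' @export
#' @examples
#' fx <- generate_universe(fixture_spec(seed = 1))
#' cand <- generate_enriched_candidates(fx$universe, fx$truth, n_candidates = 20)
#' enrich_global(cand, fx$universe)
enrich_global <- function(candidates, universe,
                          adjust = c("none", "benjamini_hochberg")) {
  assert_universe(universe)
  adjust <- match.arg(adjust)
  if (length(candidates) == 0) abort_input("candidate gene set is empty")
  enrich_table(as.character(candidates), universe$gene_map, universe$records, adjust)
}

#' Hypergeometric over-representation against the network background
#'
#' Like [enrich_global()], but the background is restricted to the genes of
#' the pathways inside a constructed leveled network, and only those
#' pathways are tested.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param network A [build_network()] result, or a `level_assignment`.
#' @param universe The [pathway_universe()] the network was built from.
#' @inheritParams enrich_global
#' @return A tibble of class `enrichment_result`.
#' @export
enrich_network <- function(candidates, network, universe,
                           adjust = c("none", "benjamini_hochberg")) {
  assert_universe(universe)
  adjust <- match.arg(adjust)
  if (length(candidates) == 0) abort_input("candidate gene set is empty")
  pathways <- if (inherits(network, "leveled_network")) {
    network$assignment$pathway_id
  } else if (inherits(network, "level_assignment")) {
    network$pathway_id
  } else {
    abort_input("`network` must be a leveled_network or level_assignment")
  }
  if (length(pathways) == 0) abort_input("network contains no pathways")
  gene_map <- universe$gene_map[universe$gene_map$pathway_id %in% pathways, ]
  if (nrow(gene_map) == 0) {
    abort_input("network pathways carry no gene annotations; nothing to test")
  }
  enrich_table(as.character(candidates), gene_map, universe$records, adjust)
}

#' Gene and pathway occurrence tables
#'
#' For a candidate gene set, counts in how many scope pathways each
#' candidate occurs and how many candidates each scope pathway holds. The
#' scope is either the whole universe or a constructed network.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param scope A [pathway_universe()] or a [build_network()] result.
#' @param universe Required when `scope` is a network: its universe.
#' @return List of two tibbles: `genes` (`gene_id`, `pathway_count`) and
#'   `pathways` (`pathway_id`, `gene_count`), sorted by count descending
#'   then id. Empty candidate sets yield zero-row tables.
#' @export
occurrence_table <- function(candidates, scope, universe = NULL) {
  candidates <- unique(as.character(candidates))
  gene_map <- if (is_pathway_universe(scope)) {
    scope$gene_map
  } else if (inherits(scope, "leveled_network")) {
    assert_universe(universe)
    universe$gene_map[universe$gene_map$pathway_id %in% scope$assignment$pathway_id, ]
  } else {
    abort_input("`scope` must be a pathway_universe or leveled_network")
  }
  hits <- gene_map[gene_map$gene_id %in% candidates, ]
  genes <- hits |>
    dplyr::count(.data$gene_id, name = "pathway_count") |>
    dplyr::arrange(dplyr::desc(.data$pathway_count), .data$gene_id)
  pathways <- hits |>
    dplyr::count(.data$pathway_id, name = "gene_count") |>
    dplyr::arrange(dplyr::desc(.data$gene_count), .data$pathway_id)
  list(genes = genes, pathways = pathways)
}
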