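#' Expand first-level pathways into an n-level assignment
#'
#' Breadth-first expansion over the undirected pathway link graph: the
#' user-chosen first-level (1L) pathways sit at level 1, and each further
#' level holds the pathways adjacent to the previous one that were not
#' reached earlier. Equivalently, a pathway's level is one plus its minimal
#' undirected distance to the nearest 1L pathway; pathways at distance
#' `>= n_levels` are excluded. With `n_levels = 1` only the 1L pathways form
#' the network. A multiply-reachable pathway takes its minimal level and
#' never appears twice.
#'
#' @param universe A [pathway_universe()].
#' @param first_level Character vector of 1L pathway ids (reference
#'   `map`-prefixed ids accepted).
#' @param n_levels Number of levels to investigate (integer `>= 1`). Values
#'   above `max_levels` are capped with a warning.
#' @param max_levels Safety cap on `n_levels` (a dense pathway graph
#'   saturates within a few breadth-first steps).
#' @return A tibble of class `level_assignment` with columns `pathway_id`,
#'   `level`, sorted by (`level`, `pathway_id`); attributes `first_level`
#'   and `n_levels`.
#' @export
#' @examples
#' fx <- generate_universe(fixture_spec(seed = 1))
#' expand_levels(fx$universe, fx$truth$first_level, n_levels = 2)
expand_levels <- function(universe, first_level, n_levels, max_levels = 10L) {
  assert_universe(universe)
  if (length(first_level) == 0) abort_input("first_level must be non-empty")
  first_level <- unique(normalize_pathway_ids(first_level, universe$organism$code))
  missing <- setdiff(first_level, universe$records$pathway_id)
  if (length(missing) > 0) {
    abort_input(sprintf("first-level pathway(s) not in universe: %s",
                        paste(missing, collapse = ", ")))
  }
  if (!is.numeric(n_levels) || length(n_levels) != 1 || n_levels < 1 ||
      n_levels != as.integer(n_levels)) {
    abort_input("n_levels must be a single integer >= 1")
  }
  n_levels <- as.integer(n_levels)
  if (n_levels > max_levels) {
    warning(sprintf("n_levels = %d capped at max_levels = %d", n_levels, max_levels),
            call. = FALSE)
    n_levels <- as.integer(max_levels)
  }

  # hand-rolled BFS with first-assignment-wins; adjacency from the canonical
  # undirected edge list
  adj <- split(
    c(universe$edges$to, universe$edges$from),
    c(universe$edges$from, universe$edges$to)
  )
  level_of <- stats::setNames(rep.int(1L, length(first_level)), sort(first_level))
  frontier <- names(level_of)
  k <- 1L
  while (k < n_levels && length(frontier) > 0) {
    k <- k + 1L
    nxt <- sort(unique(unlist(adj[frontier], use.names = FALSE)))
    nxt <- setdiff(nxt, names(level_of))
    if (length(nxt) > 0) {
      level_of <- c(level_of, stats::setNames(rep.int(k, length(nxt)), nxt))
    }
    frontier <- nxt
  }

  out <- dplyr::arrange(
    tibble::tibble(pathway_id = names(level_of), level = as.integer(level_of)),
    .data$level, .data$pathway_id
  )
  structure(out,
            first_level = sort(first_level),
            n_levels = n_levels,
            class = c("level_assignment", class(tibble::tibble())))
}

#' Build the leveled gene/pathway network
#'
#' Attaches candidate genes to the pathways of a level assignment: a gene
#' attaches to every network pathway it is annotated to (possibly at several
#' levels). Pathway edges are the universe's link edges restricted to
#' assigned pathways.
#'
#' @param universe A [pathway_universe()].
#' @param assignment A [expand_levels()] result built from `universe`.
#' @param genes A `prepared_genes` object (see [prepare_gene_list()]), a
#'   data frame with `external_id`/`entrez_id` columns, or a bare character
#'   vector of entrez ids.
#' @return An object of class `leveled_network`: list with `assignment`,
#'   `pathway_edges` (tibble `from`, `to`), `attachments` (tibble `gene_id`,
#'   `external_id`, `pathway_id`, `pathway_title`, `level`), `genes` (the
#'   deduplicated kept candidate tibble), `organism`, and the universe
#'   `version_stamp`.
#' @export
#' @examples
#' fx <- generate_universe(fixture_spec(seed = 1))
#' asg <- expand_levels(fx$universe, fx$truth$first_level, n_levels = 2)
#' genes <- unique(fx$universe$gene_map$gene_id)[1:10]
#' net <- build_network(fx$universe, asg, genes)
#' glance(net)
build_network <- function(universe, assignment, genes) {
  assert_universe(universe)
  if (!inherits(assignment, "level_assignment")) {
    abort_input("`assignment` must come from expand_levels()")
  }
  prep <- as_prepared_genes(genes)
  kept <- kept_genes(prep)
  kept <- kept[!duplicated(kept$entrez_id), ]

  attachments <- universe$gene_map |>
    dplyr::filter(.data$gene_id %in% kept$entrez_id,
                  .data$pathway_id %in% assignment$pathway_id) |>
    dplyr::left_join(tibble::as_tibble(assignment), by = "pathway_id") |>
    dplyr::left_join(universe$records, by = "pathway_id") |>
    dplyr::left_join(dplyr::rename(kept, gene_id = "entrez_id"), by = "gene_id") |>
    dplyr::select("gene_id", "external_id", "pathway_id",
                  pathway_title = "title", "level") |>
    dplyr::arrange(.data$level, .data$pathway_id, .data$gene_id)

  pathway_edges <- dplyr::filter(
    universe$edges,
    .data$from %in% assignment$pathway_id & .data$to %in% assignment$pathway_id
  )

  structure(
    list(
      assignment = assignment,
      pathway_edges = pathway_edges,
      attachments = attachments,
      genes = kept,
      organism = universe$organism,
      version_stamp = universe$version_stamp
    ),
    class = "leveled_network"
  )
}

#' @export
print.leveled_network <- function(x, ...) {
  cat(sprintf(
    "<leveled_network> %d pathways over %d level(s) (1L: %s)\n  %d pathway links; %d of %d candidate genes highlighted (%d attachments)\n",
    nrow(x$assignment), attr(x$assignment, "n_levels"),
    paste(attr(x$assignment, "first_level"), collapse = ", "),
    nrow(x$pathway_edges), length(unique(x$attachments$gene_id)),
    nrow(x$genes), nrow(x$attachments)
  ))
  invisible(x)
}

#' Partition candidate genes by their fate in the analysis
#'
#' Every candidate gene falls in exactly one class: `highlighted` (attached
#' to at least one network pathway), `outside_network` (annotated only to
#' pathways not reached within the investigated levels), `no_pathway`
#' (known to the resource but not assigned to any pathway yet), or
#' `not_in_db` (absent from the resource entirely).
#'
#' @param universe A [pathway_universe()].
#' @param network A [build_network()] result built from `universe`.
#' @param genes The same candidate genes the network was built from.
#' @return Tibble with columns `gene_id`, `external_id`, `class`
#'   (factor with the four levels above).
#' @export
classify_genes <- function(universe, network, genes) {
  assert_universe(universe)
  prep <- as_prepared_genes(genes)
  kept <- kept_genes(prep)
  kept <- kept[!duplicated(kept$entrez_id), ]

  annotated <- unique(universe$gene_map$gene_id)
  highlighted <- unique(network$attachments$gene_id)

  cls <- dplyr::case_when(
    kept$entrez_id %in% highlighted ~ "highlighted",
    kept$entrez_id %in% annotated ~ "outside_network",
    kept$entrez_id %in% universe$known_genes ~ "no_pathway",
    TRUE ~ "not_in_db"
  )
  tibble::tibble(
    gene_id = kept$entrez_id,
    external_id = kept$external_id,
    class = factor(cls, levels = c("highlighted", "outside_network",
                                   "no_pathway", "not_in_db"))
  )
}

#' Per-level tables of highlighted genes
#'
#' One table per investigated level, in the style of the per-level text
#' files of the original workflow: columns `gene_id`, `external_id`,
#' `pathway_id`, `pathway_title`, `level`, rows sorted by
#' (`pathway_id`, `gene_id`). Levels with no highlighted genes yield a
#' zero-row table.
#'
#' @param network A [build_network()] result.
#' @return Named list of tibbles (`genes_1L`, `genes_2L`, ...).
#' @export
per_level_tables <- function(network) {
  if (!inherits(network, "leveled_network")) {
    abort_input("`network` must come from build_network()")
  }
  n <- attr(network$assignment, "n_levels")
  empty <- network$attachments[0, ]
  out <- purrr::map(seq_len(n), function(k) {
    tab <- dplyr::filter(network$attachments, .data$level == k)
    if (nrow(tab) == 0) return(empty)
    dplyr::arrange(tab, .data$pathway_id, .data$gene_id)
  })
  stats::setNames(out, sprintf("genes_%dL", seq_len(n)))
}

#' Write per-level tables and the network JSON to a directory
#'
#' @param network A [build_network()] result.
#' @param directory Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_level_tables <- function(network, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  tabs <- per_level_tables(network)
  paths <- purrr::imap_chr(tabs, function(tab, nm) {
    p <- file.path(directory, paste0(nm, ".tsv"))
    write_sorted_tsv(tab, p)
    p
  })
  invisible(unname(paths))
}

#' Serialize a leveled network as JSON
#'
#' Nodes carry `id`, `kind` (`"pathway"`/`"gene"`) and `level` (pathway
#' nodes only); edges carry `from`/`to` and cover both pathway links and
#' gene attachments. The JSON is deterministic and can be read back with
#' [read_network_json()].
#'
#' @param network A [build_network()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  doc <- list(
    organism = network$organism$code,
    n_levels = attr(network$assignment, "n_levels"),
    first_level = attr(network$assignment, "first_level"),
    nodes = dplyr::bind_rows(
      tibble::tibble(id = network$assignment$pathway_id, kind = "pathway",
                     level = network$assignment$level),
      tibble::tibble(id = sort(unique(network$attachments$gene_id)),
                     kind = "gene", level = NA_integer_)
    ),
    edges = dplyr::bind_rows(
      network$pathway_edges,
      tibble::tibble(from = network$attachments$gene_id,
                     to = network$attachments$pathway_id)
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a network JSON written by [write_network_json()]
#'
#' Reconstructs the level assignment (and, for enrichment, the set of
#' network pathways) from the serialized node list.
#'
#' @param path JSON file.
#' @return A tibble of class `level_assignment`.
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- tibble::as_tibble(doc$nodes)
  pw <- nodes[nodes$kind == "pathway", ]
  structure(
    dplyr::arrange(tibble::tibble(pathway_id = pw$id, level = as.integer(pw$level)),
                   .data$level, .data$pathway_id),
    first_level = sort(unlist(doc$first_level)),
    n_levels = as.integer(doc$n_levels),
    class = c("level_assignment", class(tibble::tibble()))
  )
}
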