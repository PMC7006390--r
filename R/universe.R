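#' Construct an offline pathway universe
#'
#' A pathway universe is the offline stand-in for a live KEGG interrogation:
#' an undirected pathway-to-pathway link graph, a gene-to-pathway annotation
#' map, pathway titles, and an organism manifest. All pathway identifiers are
#' normalized to the organism prefix (`map`-prefixed reference ids are
#' rewritten). Link rows `(a,b)` and `(b,a)` collapse to one undirected edge
#' and self-links are dropped, because pathway relations are used without
#' reconstructing their direction.
#'
#' @param records Data frame with columns `pathway_id`, `title` (one row per
#'   pathway; titles must be non-empty).
#' @param links Data frame with columns `from`, `to`: pathway link pairs.
#' @param gene_map Data frame with columns `gene_id` (entrez-style numeric
#'   text), `pathway_id`. May have zero rows.
#' @param organism_code,organism_name Organism code (2--4 lowercase letters)
#'   and free-text species name.
#' @param known_genes Optional character vector of gene ids known to the
#'   resource even when not (yet) assigned to any pathway. Genes appearing in
#'   `gene_map` are always known.
#' @param version_stamp Non-empty free text recording the snapshot provenance
#'   (fixtures stamp their seed).
#' @return An object of class `pathway_universe`: a list with elements
#'   `organism` (list `code`, `name`), `records`, `edges`, `gene_map` (all
#'   tibbles), `known_genes` (character), `version_stamp`.
#' @export
#' @examples
#' u <- pathway_universe(
#'   records = data.frame(pathway_id = c("hsa00010", "hsa00020"),
#'                        title = c("Glycolysis", "TCA cycle")),
#'   links = data.frame(from = "hsa00010", to = "hsa00020"),
#'   gene_map = data.frame(gene_id = "226", pathway_id = "hsa00010"),
#'   organism_code = "hsa", organism_name = "Homo sapiens",
#'   version_stamp = "example"
#' )
#' u
pathway_universe <- function(records, links, gene_map,
                             organism_code, organism_name = organism_code,
                             known_genes = character(),
                             version_stamp = "unstamped") {
  if (!is_organism_code(organism_code)) {
    abort_input(sprintf("invalid organism code: '%s'", organism_code))
  }
  if (!nzchar(version_stamp)) abort_input("version_stamp must be non-empty")

  records <- tibble::as_tibble(records)[c("pathway_id", "title")]
  records$pathway_id <- normalize_pathway_ids(records$pathway_id, organism_code)
  if (anyDuplicated(records$pathway_id)) {
    abort_input("duplicate pathway ids in records")
  }
  if (any(!nzchar(records$title) | is.na(records$title))) {
    abort_input("pathway titles must be non-empty")
  }
  records <- dplyr::arrange(records, .data$pathway_id)

  links <- tibble::as_tibble(links)
  if (nrow(links) > 0) {
    links$from <- normalize_pathway_ids(links$from, organism_code)
    links$to <- normalize_pathway_ids(links$to, organism_code)
  } else {
    links <- tibble::tibble(from = character(), to = character())
  }
  edges <- canonicalize_edges(links$from, links$to)
  unknown <- setdiff(c(edges$from, edges$to), records$pathway_id)
  if (length(unknown) > 0) {
    abort_input(sprintf(
      "link edge references unknown pathway(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }

  gene_map <- tibble::as_tibble(gene_map)
  if (nrow(gene_map) > 0) {
    gene_map <- gene_map[c("gene_id", "pathway_id")]
    gene_map$gene_id <- as.character(gene_map$gene_id)
    gene_map$pathway_id <- normalize_pathway_ids(gene_map$pathway_id, organism_code)
    bad_gene <- gene_map$gene_id[!is_entrez_id(gene_map$gene_id)]
    if (length(bad_gene) > 0) {
      abort_input(sprintf(
        "gene ids must be entrez-style numeric text; offending: %s",
        paste(utils::head(unique(bad_gene), 5), collapse = ", ")
      ))
    }
    unknown_p <- setdiff(gene_map$pathway_id, records$pathway_id)
    if (length(unknown_p) > 0) {
      abort_input(sprintf(
        "gene map references unknown pathway(s): %s",
        paste(unknown_p, collapse = ", ")
      ))
    }
    gene_map <- dplyr::distinct(dplyr::arrange(gene_map, .data$gene_id, .data$pathway_id))
  } else {
    gene_map <- tibble::tibble(gene_id = character(), pathway_id = character())
  }

  known_genes <- sort(unique(c(as.character(known_genes), gene_map$gene_id)))

  structure(
    list(
      organism = list(code = organism_code, name = organism_name),
      records = records,
      edges = edges,
      gene_map = gene_map,
      known_genes = known_genes,
      version_stamp = version_stamp
    ),
    class = "pathway_universe"
  )
}

#' @export
print.pathway_universe <- function(x, ...) {
  cat(sprintf(
    "<pathway_universe> %s (%s)\n  %d pathways, %d links, %d gene-pathway annotations, %d known genes\n  version: %s\n",
    x$organism$code, x$organism$name, nrow(x$records), nrow(x$edges),
    nrow(x$gene_map), length(x$known_genes), x$version_stamp
  ))
  invisible(x)
}

is_pathway_universe <- function(x) inherits(x, "pathway_universe")

assert_universe <- function(x) {
  if (!is_pathway_universe(x)) abort_input("expected a `pathway_universe` object")
  invisible(x)
}

#' Neighbors of a pathway in the undirected link graph
#'
#' @param universe A [pathway_universe()].
#' @param pathway_id A single pathway id (reference-prefixed ids accepted).
#' @return Sorted character vector of adjacent pathway ids.
#' @export
universe_neighbors <- function(universe, pathway_id) {
  assert_universe(universe)
  p <- normalize_pathway_ids(pathway_id, universe$organism$code)
  sort(unique(c(
    universe$edges$to[universe$edges$from == p],
    universe$edges$from[universe$edges$to == p]
  )))
}

#' List pathways in a universe, optionally filtered by title
#'
#' The offline equivalent of retrieving the list of all investigable
#' pathways: returns pathway records sorted by id, with an optional
#' case-insensitive substring filter on the title.
#'
#' @param universe A [pathway_universe()].
#' @param title_filter Optional text; case-insensitive substring match.
#' @return Tibble with columns `pathway_id`, `title` (possibly zero rows).
#' @export
#' @examples
#' u <- generate_universe(fixture_spec(seed = 1))$universe
#' list_pathways(u)
list_pathways <- function(universe, title_filter = NULL) {
  assert_universe(universe)
  out <- dplyr::arrange(universe$records, .data$pathway_id)
  if (!is.null(title_filter)) {
    out <- dplyr::filter(
      out,
      stringr::str_detect(.data$title, stringr::fixed(title_filter, ignore_case = TRUE))
    )
  }
  out
}

#' Bundled manifest of common KEGG organism codes
#'
#' A small built-in organism manifest used by [resolve_species()] when the
#' query is not resolved against a loaded universe.
#'
#' @return Tibble with columns `organism_code`, `organism_name`.
#' @export
species_manifest <- function() {
  tibble::tribble(
    ~organism_code, ~organism_name,
    "hsa", "Homo sapiens (human)",
    "mmu", "Mus musculus (house mouse)",
    "rno", "Rattus norvegicus (rat)",
    "bta", "Bos taurus (cattle)",
    "ssc", "Sus scrofa (pig)",
    "gga", "Gallus gallus (chicken)",
    "dre", "Danio rerio (zebrafish)",
    "dme", "Drosophila melanogaster (fruit fly)",
    "cel", "Caenorhabditis elegans (nematode)",
    "sce", "Saccharomyces cerevisiae (budding yeast)"
  )
}

#' Resolve a species query to an organism code
#'
#' An exact code match wins; otherwise a unique case-insensitive substring
#' match on the species name is required. Ambiguity and no-match are errors.
#'
#' @param manifest A [pathway_universe()], or a data frame with columns
#'   `organism_code`, `organism_name` (default: [species_manifest()]).
#' @param query Species name fragment or organism code.
#' @return A single organism code.
#' @export
#' @examples
#' resolve_species(query = "hsa")
#' resolve_species(query = "zebrafish")
resolve_species <- function(manifest = species_manifest(), query) {
  if (is_pathway_universe(manifest)) {
    manifest <- tibble::tibble(
      organism_code = manifest$organism$code,
      organism_name = manifest$organism$name
    )
  }
  manifest <- tibble::as_tibble(manifest)
  if (query %in% manifest$organism_code) {
    return(query)
  }
  hits <- dplyr::filter(
    manifest,
    stringr::str_detect(.data$organism_name, stringr::fixed(query, ignore_case = TRUE))
  )
  if (nrow(hits) == 0) {
    abort_input(sprintf("no species matching '%s'", query),
                class = "pathlevels_not_found")
  }
  if (nrow(hits) > 1) {
    abort_input(sprintf(
      "ambiguous species query '%s'; candidates: %s",
      query,
      paste(sprintf("%s (%s)", hits$organism_code, hits$organism_name), collapse = "; ")
    ), class = "pathlevels_ambiguous")
  }
  hits$organism_code
}
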