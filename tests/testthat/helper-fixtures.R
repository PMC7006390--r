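# Shared in-code fixtures and independent oracles.

# tiny hand-built universe: chain A-B-C-D plus an isolated pathway E
chain_universe <- function() {
  ids <- sprintf("hsa%05d", 1:5)
  pathway_universe(
    records = tibble::tibble(
      pathway_id = ids,
      title = c("Alpha signaling", "Beta metabolism", "Gamma repair",
                "Delta transport", "Epsilon island")
    ),
    links = tibble::tibble(from = ids[1:3], to = ids[2:4]),
    gene_map = tibble::tibble(
      gene_id = c("11", "12", "12", "13", "14", "15"),
      pathway_id = c(ids[1], ids[2], ids[3], ids[3], ids[4], ids[5])
    ),
    organism_code = "hsa", organism_name = "Homo sapiens",
    known_genes = c("77"),  # known but unassigned
    version_stamp = "test-chain"
  )
}

# independent shortest-path level oracle (igraph, not the package's BFS)
oracle_levels <- function(universe, first_level, n_levels) {
  g <- igraph::graph_from_data_frame(
    universe$edges, directed = FALSE,
    vertices = universe$records["pathway_id"]
  )
  d <- igraph::distances(g, v = first_level)
  min_d <- apply(d, 2, min)
  keep <- is.finite(min_d) & min_d <= n_levels - 1
  out <- tibble::tibble(pathway_id = colnames(d)[keep],
                        level = as.integer(min_d[keep] + 1))
  dplyr::arrange(out, .data$level, .data$pathway_id)
}

# exhaustive hypergeometric upper-tail oracle: enumerate every n-subset of an
# N-element urn whose first K elements are successes, and count draws with at
# least k successes. Exact rational counts; independent of stats::phyper.
hyper_oracle <- function(k, K, n, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  sum(succ >= k) / ncol(draws)
}

# drop the level_assignment class/attributes for value comparison
assignment_table <- function(a) {
  tibble::tibble(pathway_id = a$pathway_id, level = as.integer(a$level))
}

read_file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)

expect_same_bytes <- function(a, b) {
  expect_identical(read_file_bytes(a), read_file_bytes(b))
}
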