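test_that("hypergeometric upper tail matches the worked urn case and degenerate urns", {
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(2, 10, 2, 10), 1)  # K = N: every draw succeeds
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "k <= min")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "k <= min|K <= N")
  expect_error(hypergeom_upper_tail(-1, 4, 5, 10), "non-negative")
})

test_that("upper tail agrees with exhaustive enumeration for every urn with N <= 9", {
  # full sweep to N = 12 lives in the acceptance suite; this covers N <= 9
  for (N in 1:9) {
    for (n in 0:N) {
      for (K in 0:N) {
        k <- 0:min(K, n)
        got <- hypergeom_upper_tail(k, K, n, N)
        want <- vapply(k, hyper_oracle, numeric(1), K = K, n = n, N = N)
        expect_equal(got, want, tolerance = 1e-12,
                     info = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("upper tail is monotone in k and complementary to the lower tail", {
  for (case in list(c(5, 8, 20), c(10, 10, 30), c(3, 12, 15))) {
    K <- case[1]; n <- case[2]; N <- case[3]
    k <- 0:min(K, n)
    p <- hypergeom_upper_tail(k, K, n, N)
    expect_true(all(diff(p) <= 1e-15))
    for (kk in k[k >= 1]) {
      expect_equal(hypergeom_upper_tail(kk, K, n, N) +
                     stats::phyper(kk - 1, K, N - K, n),
                   1, tolerance = 1e-12)
    }
  }
})

test_that("global enrichment ranks a planted over-represented pathway first", {
  for (seed in c(81, 82, 83)) {
    fx <- generate_universe(fixture_spec(seed = seed, n_pathways = 25))
    cand <- generate_enriched_candidates(fx$universe, fx$truth,
                                         n_candidates = 25, fraction_in = 0.8)
    res <- enrich_global(cand, fx$universe)
    expect_equal(res$pathway_id[1], fx$truth$enriched_pathway,
                 info = paste("seed", seed))
    # contract checks: sorted by p, complete counts, K >= 1 everywhere
    expect_true(!is.unsorted(res$p_value))
    expect_true(all(res$K >= 1))
    expect_true(all(res$k <= pmin(res$K, res$n)))
    expect_equal(unique(res$N), length(unique(fx$universe$gene_map$gene_id)))
  }
})

test_that("degenerate single-pathway universe yields p = 1 and candidates outside the background are counted", {
  u <- pathway_universe(
    records = tibble::tibble(pathway_id = "hsa00001", title = "Only"),
    links = tibble::tibble(from = character(), to = character()),
    gene_map = tibble::tibble(gene_id = as.character(1:6), pathway_id = "hsa00001"),
    organism_code = "hsa", version_stamp = "t"
  )
  res <- enrich_global(c("1", "2", "999"), u)
  expect_equal(nrow(res), 1)
  expect_equal(res$p_value, 1)                      # k = n, K = N
  expect_equal(attr(res, "candidates_outside_background"), 1L)
  expect_error(enrich_global("999", u), "id")       # no overlap at all
  expect_error(enrich_global(character(), u), "empty")
})

test_that("Benjamini-Hochberg adjustment matches p.adjust and is off by default", {
  fx <- generate_universe(fixture_spec(seed = 84, n_pathways = 20))
  cand <- generate_enriched_candidates(fx$universe, fx$truth)
  raw <- enrich_global(cand, fx$universe)
  expect_true(all(is.na(raw$p_adjusted)))
  adj <- enrich_global(cand, fx$universe, adjust = "benjamini_hochberg")
  expect_equal(adj$p_adjusted, stats::p.adjust(adj$p_value, "BH"))
})

test_that("network-restricted enrichment tests network pathways against the network background", {
  fx <- generate_universe(fixture_spec(seed = 85, n_pathways = 25))
  asg <- expand_levels(fx$universe, fx$truth$first_level, 2)
  net <- build_network(fx$universe, asg, unique(fx$universe$gene_map$gene_id)[1:15])
  cand <- generate_enriched_candidates(fx$universe, fx$truth)
  gm <- fx$universe$gene_map
  net_bg <- unique(gm$gene_id[gm$pathway_id %in% asg$pathway_id])
  if (length(intersect(cand, net_bg)) > 0) {
    res <- enrich_network(cand, net, fx$universe)
    expect_setequal(res$pathway_id, asg$pathway_id)
    expect_equal(unique(res$N), length(net_bg))
  }
  # when the network spans the whole universe the two backgrounds coincide
  asg_all <- expand_levels(fx$universe, fx$truth$first_level, 10)
  if (setequal(asg_all$pathway_id, fx$universe$records$pathway_id)) {
    g <- enrich_global(cand, fx$universe)
    nres <- enrich_network(cand, asg_all, fx$universe)
    m <- dplyr::inner_join(tibble::as_tibble(g), tibble::as_tibble(nres),
                           by = "pathway_id")
    expect_equal(m$p_value.x, m$p_value.y)
  }
  # single-pathway network: K = N
  one <- structure(tibble::tibble(pathway_id = fx$truth$enriched_pathway, level = 1L),
                   first_level = fx$truth$enriched_pathway, n_levels = 1L,
                   class = c("level_assignment", class(tibble::tibble())))
  in_genes <- unique(gm$gene_id[gm$pathway_id == fx$truth$enriched_pathway])
  r1 <- enrich_network(in_genes[1:3], one, fx$universe)
  expect_equal(r1$K, r1$N)
  expect_equal(r1$p_value, 1)
  # all candidates outside the network background is an error
  outside <- setdiff(unique(gm$gene_id), in_genes)
  if (length(outside) > 0) {
    expect_error(enrich_network(setdiff(fx$truth$unknown_gene_pool, net_bg), one,
                                fx$universe), "id|overlap")
  }
})

test_that("occurrence tables count incidences consistently in both directions", {
  u <- chain_universe()
  occ <- occurrence_table(c("12", "13", "999"), u)
  expect_equal(occ$genes$pathway_count[occ$genes$gene_id == "12"], 2L)
  expect_equal(sum(occ$genes$pathway_count), sum(occ$pathways$gene_count))
  expect_equal(sum(occ$genes$pathway_count),
               sum(u$gene_map$gene_id %in% c("12", "13")))
  empty <- occurrence_table(character(), u)
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$pathways), 0)
  # network scope restricts the relation
  asg <- expand_levels(u, "hsa00001", 2)
  net <- build_network(u, asg, c("12", "13"))
  occ_net <- occurrence_table(c("12", "13"), net, u)
  expect_equal(occ_net$genes$pathway_count[occ_net$genes$gene_id == "12"], 1L)
})
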