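test_that("expand_levels walks a chain graph one level per step", {
  u <- chain_universe()  # hsa00001 - 00002 - 00003 - 00004, 00005 isolated
  a2 <- expand_levels(u, "hsa00001", 2)
  expect_equal(assignment_table(a2),
               tibble::tibble(pathway_id = c("hsa00001", "hsa00002"), level = 1:2))
  a1 <- expand_levels(u, "hsa00001", 1)
  expect_equal(a1$pathway_id, "hsa00001")  # n = 1: only the 1L pathways
  expect_equal(a1$level, 1L)
  a4 <- expand_levels(u, "hsa00001", 4)
  expect_equal(a4$level[a4$pathway_id == "hsa00004"], 4L)
  expect_false("hsa00005" %in% a4$pathway_id)  # unreachable stays out
})

test_that("expand_levels validates its inputs and caps the level count", {
  u <- chain_universe()
  expect_error(expand_levels(u, "hsa99999", 2), "hsa99999")
  expect_error(expand_levels(u, character(), 2), "non-empty")
  expect_error(expand_levels(u, "hsa00001", 0), "integer >= 1")
  expect_warning(a <- expand_levels(u, "hsa00001", 99), "capped")
  expect_lte(max(a$level), 10)
  # map-prefixed 1L ids are accepted and rewritten
  am <- expand_levels(u, "map00001", 2)
  expect_true("hsa00001" %in% am$pathway_id)
})

test_that("levels equal shortest-path distance + 1 on random universes", {
  for (seed in 1:25) {
    spec <- fixture_spec(seed = seed, n_pathways = 5 + (seed * 7) %% 41,
                         edge_probability = c(0, 0.05, 0.15)[seed %% 3 + 1])
    fx <- generate_universe(spec)
    n <- 1 + seed %% 4
    got <- expand_levels(fx$universe, fx$truth$first_level, n)
    want <- oracle_levels(fx$universe, fx$truth$first_level, n)
    expect_equal(assignment_table(got), assignment_table(want),
                 info = paste("seed", seed))
  }
})

test_that("assignments and highlighted genes are nested as n grows", {
  fx <- generate_universe(fixture_spec(seed = 21, n_pathways = 30))
  genes <- unique(fx$universe$gene_map$gene_id)
  prev_asg <- NULL
  prev_hl <- character()
  for (n in 1:3) {
    asg <- expand_levels(fx$universe, fx$truth$first_level, n)
    net <- build_network(fx$universe, asg, genes)
    hl <- unique(net$attachments$gene_id)
    if (!is.null(prev_asg)) {
      shared <- dplyr::inner_join(prev_asg, asg, by = "pathway_id")
      expect_equal(shared$level.x, shared$level.y)   # sub-mapping, same levels
      expect_equal(nrow(shared), nrow(prev_asg))
      expect_true(all(prev_hl %in% hl))
    }
    prev_asg <- tibble::as_tibble(asg)
    prev_hl <- hl
  }
})

test_that("build_network attaches genes to every assigned pathway containing them", {
  u <- chain_universe()
  asg <- expand_levels(u, "hsa00001", 2)  # {00001:1, 00002:2}
  # gene 12 is annotated to 00002 and 00003; only 00002 is in the network
  net <- build_network(u, asg, c("12", "15"))
  expect_equal(net$attachments$gene_id, "12")
  expect_equal(net$attachments$pathway_id, "hsa00002")
  expect_equal(net$attachments$level, 2L)
  # gene annotated to two in-network pathways attaches to both
  asg3 <- expand_levels(u, "hsa00002", 2)
  net3 <- build_network(u, asg3, "12")
  expect_setequal(net3$attachments$pathway_id, c("hsa00002", "hsa00003"))
  # pathway edges are the universe edges among assigned pathways
  expect_equal(nrow(net3$pathway_edges), 2)
})

test_that("planted fixture genes are recovered at their planted level", {
  fx <- generate_universe(fixture_spec(seed = 31, n_pathways = 25))
  asg <- expand_levels(fx$universe, fx$truth$first_level, fx$truth$n_levels)
  genes <- unique(fx$universe$gene_map$gene_id)
  net <- build_network(fx$universe, asg, genes)
  # brute-force expected attachments from the raw gene map
  want <- fx$universe$gene_map[fx$universe$gene_map$pathway_id %in% asg$pathway_id, ]
  got <- net$attachments[c("gene_id", "pathway_id")]
  expect_equal(dplyr::arrange(got, gene_id, pathway_id),
               dplyr::arrange(want, gene_id, pathway_id),
               ignore_attr = TRUE)
})

test_that("classify_genes partitions candidates into the four exclusion classes", {
  u <- chain_universe()
  asg <- expand_levels(u, "hsa00001", 2)
  cand <- c("11",  # in network -> highlighted
            "15",  # only in hsa00005, outside levels -> outside_network
            "77",  # known, no pathway
            "999") # absent entirely
  net <- build_network(u, asg, cand)
  part <- classify_genes(u, net, cand)
  expect_equal(as.character(part$class),
               c("highlighted", "outside_network", "no_pathway", "not_in_db"))
  expect_equal(nrow(part), length(cand))
})

test_that("planted partitions are recovered exactly over random fixtures", {
  for (seed in 41:55) {
    fx <- generate_universe(fixture_spec(seed = seed, n_pathways = 10 + seed %% 16))
    counts <- c(highlighted = 5L, outside_network = 2L,
                no_pathway = 3L, not_in_db = 4L)
    cand <- tryCatch(
      generate_candidate_list(fx$universe, fx$truth, counts),
      pathlevels_input_error = function(e) NULL  # some graphs have no outside pathways
    )
    if (is.null(cand)) {
      counts["outside_network"] <- 0L
      cand <- generate_candidate_list(fx$universe, fx$truth, counts)
    }
    asg <- expand_levels(fx$universe, fx$truth$first_level, fx$truth$n_levels)
    net <- build_network(fx$universe, asg, cand$gene_id)
    part <- classify_genes(fx$universe, net, cand$gene_id)
    expect_equal(nrow(part), sum(counts))
    got <- table(factor(part$class, levels = names(counts)))
    expect_equal(as.integer(got), unname(counts), info = paste("seed", seed))
    # the partition agrees gene-by-gene with the planted truth
    m <- dplyr::inner_join(part, cand, by = "gene_id")
    expect_equal(as.character(m$class), m$true_class, info = paste("seed", seed))
  }
})

test_that("per-level tables cover all attachments, sorted, one table per level", {
  u <- chain_universe()
  asg <- expand_levels(u, "hsa00001", 3)
  net <- build_network(u, asg, c("12", "13"))
  tabs <- per_level_tables(net)
  expect_named(tabs, c("genes_1L", "genes_2L", "genes_3L"))
  expect_equal(nrow(tabs$genes_1L), 0)  # no candidate sits at level 1
  expect_equal(sum(vapply(tabs, nrow, integer(1))), nrow(net$attachments))
  lvl3 <- tabs$genes_3L
  expect_equal(lvl3, dplyr::arrange(lvl3, pathway_id, gene_id))
  # a gene in two same-level pathways appears once per pathway
  asg2 <- expand_levels(u, "hsa00002", 2)
  net2 <- build_network(u, asg2, "12")
  tabs2 <- per_level_tables(net2)
  expect_equal(nrow(tabs2$genes_1L) + nrow(tabs2$genes_2L), 2)
})

test_that("identical inputs produce byte-identical written tables", {
  fx <- generate_universe(fixture_spec(seed = 61, n_pathways = 20))
  asg <- expand_levels(fx$universe, fx$truth$first_level, 3)
  net <- build_network(fx$universe, asg, unique(fx$universe$gene_map$gene_id))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_level_tables(net, d1)
  write_level_tables(net, d2)
  for (f in list.files(d1)) expect_same_bytes(file.path(d1, f), file.path(d2, f))
})

test_that("network JSON round-trips the level assignment", {
  fx <- generate_universe(fixture_spec(seed = 62, n_pathways = 15))
  asg <- expand_levels(fx$universe, fx$truth$first_level, 3)
  net <- build_network(fx$universe, asg, unique(fx$universe$gene_map$gene_id)[1:10])
  p <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, p)
  back <- read_network_json(p)
  expect_equal(assignment_table(back), assignment_table(asg))
  expect_equal(attr(back, "n_levels"), attr(asg, "n_levels"))
  expect_equal(attr(back, "first_level"), attr(asg, "first_level"))
})
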