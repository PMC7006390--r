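test_that("parse_kgml extracts record, linked maps and genes with prefixes stripped", {
  kgml <- paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:hsa00010" org="hsa" title="Glycolysis">\n',
    '  <entry id="1" name="path:hsa00020" type="map"/>\n',
    '  <entry id="2" name="path:hsa00030" type="map"/>\n',
    '  <entry id="3" name="path:hsa00010" type="map"/>\n',   # self-link: dropped
    '  <entry id="4" name="hsa:226 hsa:226" type="gene"/>\n',
    '  <entry id="5" name="hsa:229" type="gene"/>\n',
    '  <entry id="6" name="cpd:C00031" type="compound"/>\n',
    "</pathway>\n"
  )
  p <- suppressMessages(parse_kgml(kgml))
  expect_equal(p$record$pathway_id, "hsa00010")
  expect_equal(p$record$title, "Glycolysis")
  expect_setequal(p$linked_pathways, c("hsa00020", "hsa00030"))
  expect_setequal(p$gene_ids, c("226", "229"))
  expect_equal(unname(p$skipped["compound"]), 1L)
})

test_that("parse_kgml handles empty map sets and rejects malformed documents", {
  empty <- '<pathway name="path:hsa00010" org="hsa" title="T"><entry id="1" name="hsa:5" type="gene"/></pathway>'
  expect_length(parse_kgml(empty)$linked_pathways, 0)
  expect_error(parse_kgml("<pathway name='path:hsa00010'"), class = "pathlevels_io_error")
  expect_error(parse_kgml("<notpathway/>"), "root element")
  expect_error(parse_kgml('<pathway name="path:hsa00010" org="hsa"><entry id="1" type="gene"/></pathway>'),
               "lacks a type/name")
})

test_that("KGML written from a universe round-trips through parse_kgml", {
  fx <- generate_universe(fixture_spec(seed = 11, n_pathways = 10))
  u <- fx$universe
  for (p in u$records$pathway_id) {
    parsed <- parse_kgml(write_kgml(u, p))
    expect_identical(parsed$record$pathway_id, p)
    expect_setequal(parsed$linked_pathways, universe_neighbors(u, p))
    expect_setequal(parsed$gene_ids,
                    u$gene_map$gene_id[u$gene_map$pathway_id == p])
  }
})

test_that("snapshot save/load is an identity and saves are byte-deterministic", {
  fx <- generate_universe(fixture_spec(seed = 12, n_pathways = 15))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_snapshot(fx$universe, d1)
  u2 <- load_snapshot(d1)
  expect_identical(u2$records, fx$universe$records)
  expect_identical(u2$edges, fx$universe$edges)
  expect_identical(u2$gene_map, fx$universe$gene_map)
  expect_identical(u2$known_genes, fx$universe$known_genes)
  expect_identical(u2$version_stamp, fx$universe$version_stamp)
  save_snapshot(u2, d2)
  for (f in list.files(d1)) expect_same_bytes(file.path(d1, f), file.path(d2, f))
})

test_that("a KGML-file snapshot loads to the same universe as the flat tables", {
  fx <- generate_universe(fixture_spec(seed = 13, n_pathways = 8))
  flat <- withr::local_tempdir()
  kdir <- withr::local_tempdir()
  save_snapshot(fx$universe, flat)
  file.copy(file.path(flat, "manifest.tsv"), kdir)
  for (p in fx$universe$records$pathway_id) {
    write_kgml(fx$universe, p, file.path(kdir, paste0(p, ".xml")))
  }
  uk <- load_snapshot(kdir)
  expect_identical(uk$edges, fx$universe$edges)
  expect_identical(uk$gene_map, fx$universe$gene_map)
  expect_identical(uk$records, fx$universe$records)
})

test_that("load_snapshot collapses symmetric link rows and flags bad input", {
  d <- withr::local_tempdir()
  writeLines(c("organism_code\torganism_name\tversion_stamp", "hsa\thuman\tv1"),
             file.path(d, "manifest.tsv"))
  writeLines(c("pathway_id\ttitle", "hsa00001\tA", "hsa00002\tB", "hsa00003\tC"),
             file.path(d, "pathway_titles.tsv"))
  writeLines(c("from_id\tto_id", "hsa00001\thsa00002", "hsa00002\thsa00001",
               "hsa00002\thsa00003"),
             file.path(d, "pathway_links.tsv"))
  writeLines("gene_id\tpathway_id", file.path(d, "gene_pathways.tsv"))
  u <- load_snapshot(d)
  expect_equal(nrow(u$edges), 2)                     # (a,b)+(b,a) collapse
  expect_equal(nrow(u$gene_map), 0)                  # empty gene map is valid

  writeLines(c("from_id\tto_id", "hsa00001\thsa99999"), file.path(d, "pathway_links.tsv"))
  expect_error(load_snapshot(d), "row 2")
  file.remove(file.path(d, "pathway_links.tsv"))
  expect_error(load_snapshot(d), "pathway_links.tsv")
})

test_that("universe invariants hold: undirected symmetry and gene-map transpose", {
  u <- chain_universe()
  for (i in seq_len(nrow(u$edges))) {
    a <- u$edges$from[i]; b <- u$edges$to[i]
    expect_true(b %in% universe_neighbors(u, a))
    expect_true(a %in% universe_neighbors(u, b))
  }
  # transpose consistency, checked exhaustively
  for (g in unique(u$gene_map$gene_id)) {
    for (p in unique(u$gene_map$pathway_id)) {
      fwd <- p %in% u$gene_map$pathway_id[u$gene_map$gene_id == g]
      inv <- g %in% u$gene_map$gene_id[u$gene_map$pathway_id == p]
      expect_identical(fwd, inv)
    }
  }
})

test_that("reference map ids normalize to the organism prefix", {
  expect_equal(normalize_pathway_ids(c("map04940", "hsa00010"), "hsa"),
               c("hsa04940", "hsa00010"))
  expect_error(normalize_pathway_ids("mmu00010", "hsa"), "foreign organism")
  expect_error(normalize_pathway_ids("hsa123", "hsa"), "malformed")
})

test_that("list_pathways filters titles case-insensitively and sorts by id", {
  u <- chain_universe()
  all <- list_pathways(u)
  expect_equal(nrow(all), 5)
  expect_equal(all$pathway_id, sort(all$pathway_id))
  hit <- list_pathways(u, "beta META")
  expect_equal(hit$pathway_id, "hsa00002")
  expect_equal(nrow(list_pathways(u, "diabetes")), 0)
})

test_that("resolve_species matches codes exactly and names uniquely", {
  expect_equal(resolve_species(query = "hsa"), "hsa")
  expect_equal(resolve_species(query = "zebrafish"), "dre")
  expect_error(resolve_species(query = "zzz"), class = "pathlevels_not_found")
  man <- tibble::tibble(organism_code = c("aaa", "bbb"),
                        organism_name = c("mouse one", "mouse two"))
  err <- tryCatch(resolve_species(man, "mouse"), error = identity)
  expect_s3_class(err, "pathlevels_ambiguous")
  expect_match(conditionMessage(err), "aaa")
  expect_match(conditionMessage(err), "bbb")
  u <- chain_universe()
  expect_equal(resolve_species(u, "sapiens"), "hsa")
})
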