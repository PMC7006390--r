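#' Parameters for a synthetic pathway universe
#'
#' Defines the seeded generator of offline pathway universes with planted
#' ground truth, standing in for the trial data of a live KEGG-backed
#' analysis. The link graph is an Erdős–Rényi graph laid over a random
#' spanning-tree backbone (so it is always connected and breadth-first
#' levels are exercised); genes are drawn from a shared pool so pathways
#' overlap; a fraction of known genes carry no pathway assignment and a
#' fraction of candidate ids are absent from the universe entirely,
#' mirroring the exclusion classes seen with incomplete pathway resources.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_pathways Number of pathways (`>= 1`).
#' @param edge_probability Probability of each extra (non-backbone) link.
#' @param genes_per_pathway Integer range `c(min, max)` of genes annotated
#'   per pathway.
#' @param fraction_unannotated_genes Fraction of extra known genes with no
#'   pathway assignment, relative to the annotated gene count.
#' @param fraction_unknown_genes Reserve of synthesized gene ids absent from
#'   the universe (used for candidate lists), same relative scale.
#' @param deg_null_fraction Fraction of null (non-signal) genes in generated
#'   DEG tables.
#' @param signal_fold_change Minimum absolute fold change of planted signal
#'   DEGs.
#' @param organism_code,organism_name Synthetic organism; defaults to
#'   `"syn"`.
#' @return An object of class `fixture_spec` (a validated list).
#' @export
#' @examples
#' fixture_spec(seed = 7, n_pathways = 20)
fixture_spec <- function(seed = 1L,
                         n_pathways = 30L,
                         edge_probability = 0.08,
                         genes_per_pathway = c(4L, 12L),
                         fraction_unannotated_genes = 0.15,
                         fraction_unknown_genes = 0.15,
                         deg_null_fraction = 0.85,
                         signal_fold_change = 2,
                         organism_code = "syn",
                         organism_name = "Synthetic organism") {
  spec <- list(
    seed = as.integer(seed),
    n_pathways = as.integer(n_pathways),
    edge_probability = edge_probability,
    genes_per_pathway = as.integer(genes_per_pathway),
    fraction_unannotated_genes = fraction_unannotated_genes,
    fraction_unknown_genes = fraction_unknown_genes,
    deg_null_fraction = deg_null_fraction,
    signal_fold_change = signal_fold_change,
    organism_code = organism_code,
    organism_name = organism_name
  )
  if (is.na(spec$seed)) abort_input("seed must be an integer")
  if (spec$n_pathways < 1) abort_input("n_pathways must be >= 1")
  fracs <- c(spec$edge_probability, spec$fraction_unannotated_genes,
             spec$fraction_unknown_genes, spec$deg_null_fraction)
  if (any(!is.finite(fracs) | fracs < 0 | fracs > 1)) {
    abort_input("probabilities/fractions must lie in [0, 1]")
  }
  if (length(spec$genes_per_pathway) != 2 ||
      any(spec$genes_per_pathway < 1) ||
      spec$genes_per_pathway[1] > spec$genes_per_pathway[2]) {
    abort_input("genes_per_pathway must be a non-empty integer range c(min, max)")
  }
  if (!is.finite(spec$signal_fold_change) || spec$signal_fold_change <= 0) {
    abort_input("signal_fold_change must be positive")
  }
  if (!is_organism_code(spec$organism_code)) {
    abort_input("organism_code must be 2-4 lowercase letters")
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic pathway universe with planted ground truth
#'
#' Draws the link graph, gene annotations and known-gene registry from a
#' [fixture_spec()] and records ground truth for downstream checks: the
#' true level of every pathway relative to a designated first-level set
#' (computed with an independent shortest-path routine from igraph, not the
#' package's own breadth-first expansion), and a designated
#' enrichment-target pathway (the one with the most annotated genes).
#'
#' @param spec A [fixture_spec()].
#' @param directory Optional path: when given, the snapshot tables and a
#'   `ground_truth.tsv` are written there.
#' @return List with `universe` (a [pathway_universe()]) and `truth` (list
#'   with `first_level`, `n_levels`, `true_levels` tibble (`pathway_id`,
#'   `level`; all pathways, `NA` when unreachable within `n_levels`),
#'   `enriched_pathway`, `unknown_gene_pool`, `seed`).
#' @export
#' @examples
#' fx <- generate_universe(fixture_spec(seed = 7, n_pathways = 15))
#' fx$universe
generate_universe <- function(spec, directory = NULL) {
  if (!inherits(spec, "fixture_spec")) abort_input("`spec` must be a fixture_spec()")
  withr::with_seed(spec$seed, {
    np <- spec$n_pathways
    ids <- sprintf("%s%05d", spec$organism_code, seq_len(np))
    records <- tibble::tibble(
      pathway_id = ids,
      title = sprintf("Synthetic pathway %03d", seq_len(np))
    )

    # spanning-tree backbone, then independent extra edges
    edges <- NULL
    if (np > 1) {
      backbone <- tibble::tibble(
        from = ids[vapply(2:np, function(i) sample.int(i - 1L, 1L), integer(1))],
        to = ids[2:np]
      )
      pairs <- utils::combn(ids, 2)
      in_backbone <- paste(pmin(backbone$from, backbone$to),
                           pmax(backbone$from, backbone$to))
      all_keys <- paste(pairs[1, ], pairs[2, ])
      extra_idx <- which(!(all_keys %in% in_backbone) &
                           stats::runif(ncol(pairs)) < spec$edge_probability)
      edges <- dplyr::bind_rows(
        backbone,
        tibble::tibble(from = pairs[1, extra_idx], to = pairs[2, extra_idx])
      )
    } else {
      edges <- tibble::tibble(from = character(), to = character())
    }

    # shared gene pool so pathways overlap
    sizes <- sample(seq(spec$genes_per_pathway[1], spec$genes_per_pathway[2]),
                    np, replace = TRUE)
    pool_size <- max(2L, ceiling(sum(sizes) * 0.7))
    pool <- as.character(1000L + seq_len(pool_size))
    gene_map <- purrr::map2_dfr(ids, sizes, function(p, s) {
      tibble::tibble(gene_id = sample(pool, min(s, pool_size)), pathway_id = p)
    })

    annotated <- unique(gene_map$gene_id)
    n_unann <- ceiling(spec$fraction_unannotated_genes * length(annotated))
    unannotated <- as.character(500000L + seq_len(n_unann))
    n_unknown <- ceiling(spec$fraction_unknown_genes * length(annotated))
    unknown_pool <- as.character(900000L + seq_len(max(n_unknown, 1L)))

    universe <- pathway_universe(
      records = records,
      links = edges,
      gene_map = gene_map,
      organism_code = spec$organism_code,
      organism_name = spec$organism_name,
      known_genes = unannotated,
      version_stamp = sprintf("fixture-seed-%d", spec$seed)
    )

    # designated 1L set and true levels via an independent shortest-path
    # oracle (igraph), so breadth-first expansion can be checked against it
    n_first <- min(2L, np)
    first_level <- sort(sample(ids, n_first))
    n_levels <- 3L
    g <- igraph::graph_from_data_frame(universe$edges, directed = FALSE,
                                       vertices = records["pathway_id"])
    d <- igraph::distances(g, v = first_level)
    min_d <- apply(d, 2, min)
    lev <- ifelse(is.finite(min_d) & min_d <= n_levels - 1, min_d + 1, NA)
    true_levels <- tibble::tibble(
      pathway_id = colnames(d),
      level = as.integer(lev)
    )

    sizes_by_pathway <- dplyr::count(gene_map, .data$pathway_id)
    enriched <- sizes_by_pathway$pathway_id[which.max(sizes_by_pathway$n)]

    truth <- list(
      first_level = first_level,
      n_levels = n_levels,
      true_levels = dplyr::arrange(true_levels, .data$pathway_id),
      enriched_pathway = enriched,
      unknown_gene_pool = unknown_pool,
      seed = spec$seed
    )

    if (!is.null(directory)) {
      save_snapshot(universe, directory)
      write_sorted_tsv(
        tibble::tibble(
          key = c("first_level", "n_levels", "enriched_pathway", "seed"),
          value = c(paste(first_level, collapse = ","),
                    as.character(n_levels), enriched, as.character(spec$seed))
        ),
        file.path(directory, "ground_truth.tsv")
      )
    }

    list(universe = universe, truth = truth)
  })
}

#' Generate a candidate gene list with planted partition classes
#'
#' Draws the requested number of genes per partition class against the
#' designated first-level set and level count of the fixture's ground
#' truth, so [classify_genes()] can be checked for exact recovery:
#' `highlighted` genes are annotated to in-network pathways,
#' `outside_network` genes only to pathways beyond the investigated levels,
#' `no_pathway` genes are known but unassigned, and `not_in_db` ids are
#' synthesized absent ids.
#'
#' @param universe The fixture universe.
#' @param truth The fixture ground truth (see [generate_universe()]).
#' @param counts Named integer vector with entries `highlighted`,
#'   `outside_network`, `no_pathway`, `not_in_db` (missing entries = 0).
#' @param seed Seed for the draw; defaults to the fixture seed + 1.
#' @return Tibble with columns `gene_id`, `true_class`; the realized list
#'   size equals `sum(counts)`.
#' @export
generate_candidate_list <- function(universe, truth, counts, seed = NULL) {
  assert_universe(universe)
  want <- c(highlighted = 0L, outside_network = 0L, no_pathway = 0L, not_in_db = 0L)
  bad <- setdiff(names(counts), names(want))
  if (length(bad) > 0) {
    abort_input(sprintf("unknown partition class(es): %s", paste(bad, collapse = ", ")))
  }
  want[names(counts)] <- as.integer(counts)
  if (any(want < 0)) abort_input("counts must be non-negative")
  seed <- seed %||% (truth$seed + 1L)

  in_network <- truth$true_levels$pathway_id[!is.na(truth$true_levels$level)]
  gm <- universe$gene_map
  inside_genes <- unique(gm$gene_id[gm$pathway_id %in% in_network])
  outside_only <- setdiff(unique(gm$gene_id), inside_genes)
  unassigned <- setdiff(universe$known_genes, unique(gm$gene_id))

  avail <- c(highlighted = length(inside_genes),
             outside_network = length(outside_only),
             no_pathway = length(unassigned),
             not_in_db = length(truth$unknown_gene_pool))
  short <- names(want)[want > avail]
  if (length(short) > 0) {
    abort_input(sprintf(
      "infeasible counts: class '%s' requests %d but only %d available",
      short[1], want[short[1]], avail[short[1]]
    ))
  }

  withr::with_seed(seed, {
    pick <- function(pool, n) if (n > 0) sample(pool, n) else character()
    out <- dplyr::bind_rows(
      tibble::tibble(gene_id = pick(inside_genes, want["highlighted"]),
                     true_class = "highlighted"),
      tibble::tibble(gene_id = pick(outside_only, want["outside_network"]),
                     true_class = "outside_network"),
      tibble::tibble(gene_id = pick(unassigned, want["no_pathway"]),
                     true_class = "no_pathway"),
      tibble::tibble(gene_id = pick(truth$unknown_gene_pool, want["not_in_db"]),
                     true_class = "not_in_db")
    )
    out[sample.int(nrow(out)), ]
  })
}

#' Generate a candidate list over-representing one pathway
#'
#' Plants an enrichment signal: a given fraction of the candidates are
#' drawn from the ground truth's designated enrichment-target pathway, the
#' rest uniformly from the remaining annotated genes.
#'
#' @param universe The fixture universe.
#' @param truth The fixture ground truth.
#' @param n_candidates Total candidate count.
#' @param fraction_in Fraction drawn from the target pathway.
#' @param seed Seed; defaults to the fixture seed + 2.
#' @return Character vector of gene ids.
#' @export
generate_enriched_candidates <- function(universe, truth, n_candidates = 25L,
                                         fraction_in = 0.8, seed = NULL) {
  assert_universe(universe)
  seed <- seed %||% (truth$seed + 2L)
  target <- truth$enriched_pathway
  gm <- universe$gene_map
  in_genes <- unique(gm$gene_id[gm$pathway_id == target])
  out_genes <- setdiff(unique(gm$gene_id), in_genes)
  n_in <- min(length(in_genes), round(fraction_in * n_candidates))
  n_out <- min(length(out_genes), n_candidates - n_in)
  withr::with_seed(seed, {
    unique(c(sample(in_genes, n_in), sample(out_genes, n_out)))
  })
}

#' Generate a DEG table and pathway score list
#'
#' Null genes receive symmetric small fold changes around zero and uniform
#' p-values; planted signal genes receive `|fold change| >=
#' signal_fold_change` and p-values below 0.01, so they all survive a 0.05
#' cut-off by construction. Pathway scores cover the ground truth's
#' first-level pathways plus extra sampled ones, with both signs present so
#' both color scales are exercised.
#'
#' @param universe The fixture universe.
#' @param spec The [fixture_spec()] used to build it.
#' @param truth The fixture ground truth.
#' @param n_scored_pathways Number of scored pathways (at least the
#'   first-level set).
#' @param directory Optional path: writes `deg_table.tsv` and
#'   `pathway_scores.tsv` there.
#' @return List with `degs` (tibble `gene_id`, `external_id`,
#'   `fold_change`, `p_value`, `is_signal`) and `scores` (tibble
#'   `pathway_id`, `score`).
#' @export
generate_deg_table <- function(universe, spec, truth,
                               n_scored_pathways = 4L, directory = NULL) {
  assert_universe(universe)
  if (!inherits(spec, "fixture_spec")) abort_input("`spec` must be a fixture_spec()")
  withr::with_seed(spec$seed + 3L, {
    genes <- unique(universe$gene_map$gene_id)
    n <- length(genes)
    n_signal <- max(1L, round((1 - spec$deg_null_fraction) * n))
    is_signal <- seq_len(n) %in% sample.int(n, n_signal)

    fc_null <- stats::rnorm(n, 0, 0.5)
    fc_null[fc_null == 0] <- 0.01
    fc_signal <- (spec$signal_fold_change + stats::rexp(n, 1)) *
      sample(c(-1, 1), n, replace = TRUE)
    degs <- tibble::tibble(
      gene_id = genes,
      external_id = genes,
      fold_change = ifelse(is_signal, fc_signal, fc_null),
      p_value = ifelse(is_signal, stats::runif(n, 0, 0.009),
                       stats::runif(n)),
      is_signal = is_signal
    )

    extra <- setdiff(universe$records$pathway_id, truth$first_level)
    n_extra <- min(length(extra), max(0L, n_scored_pathways - length(truth$first_level)))
    scored <- c(truth$first_level, if (n_extra > 0) sample(extra, n_extra))
    s <- stats::rnorm(length(scored), 0, 2)
    s[s == 0] <- 0.5
    # force both signs so both the red and the green scale appear
    if (all(s > 0)) s[1] <- -abs(s[1])
    if (all(s < 0)) s[1] <- abs(s[1])
    scores <- tibble::tibble(pathway_id = scored, score = s)

    if (!is.null(directory)) {
      dir.create(directory, recursive = TRUE, showWarnings = FALSE)
      write_sorted_tsv(degs[c("gene_id", "fold_change", "p_value")] |>
                         dplyr::rename(external_id = "gene_id"),
                       file.path(directory, "deg_table.tsv"))
      write_sorted_tsv(scores, file.path(directory, "pathway_scores.tsv"))
    }
    list(degs = degs, scores = scores)
  })
}

#' Write an identity annotation table for fixture gene ids
#'
#' Fixture candidate lists use entrez-style ids directly; this helper
#' writes the matching identity annotation (external id = entrez id), with
#' a configurable number of ids mapped to no entrez id so the dropped
#' classes of [prepare_gene_list()] are exercised.
#'
#' @param gene_ids Character vector of ids to cover.
#' @param path Output TSV.
#' @param n_missing How many of them get an empty entrez id.
#' @return `path`, invisibly.
#' @export
write_identity_annotation <- function(gene_ids, path, n_missing = 0L) {
  gene_ids <- unique(as.character(gene_ids))
  entrez <- gene_ids
  if (n_missing > 0) entrez[seq_len(min(n_missing, length(entrez)))] <- NA_character_
  write_sorted_tsv(tibble::tibble(external_id = gene_ids, entrez_id = entrez), path)
  invisible(path)
}
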