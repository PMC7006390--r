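# On-disk snapshot layout (all UTF-8, LF, tab-separated, header row, sorted):
#   manifest.tsv        organism_code  organism_name  version_stamp
#   pathway_titles.tsv  pathway_id  title
#   pathway_links.tsv   from_id  to_id
#   gene_pathways.tsv   gene_id  pathway_id
#   known_genes.tsv     gene_id            (optional on load)
# Alternatively a directory of KGML *.xml files plus manifest.tsv.

snapshot_files <- c("manifest.tsv", "pathway_titles.tsv",
                    "pathway_links.tsv", "gene_pathways.tsv")

write_sorted_tsv <- function(df, path) {
  # readr::write_tsv writes LF and no quoting for plain text columns
  readr::write_tsv(df, path, eol = "\n", progress = FALSE)
}

read_snap_tsv <- function(path, col_names) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(col_names, names(df))
  if (length(missing) > 0) {
    abort_input(sprintf("%s: missing column(s) %s",
                        basename(path), paste(missing, collapse = ", ")))
  }
  df[col_names]
}

#' Save a pathway universe as a snapshot directory
#'
#' Writes the five tab-separated snapshot tables with lexicographically
#' sorted rows, so that two saves of the same universe are byte-identical
#' and `load_snapshot(save_snapshot(u))` reproduces `u`.
#'
#' @param universe A [pathway_universe()].
#' @param directory Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
save_snapshot <- function(universe, directory) {
  assert_universe(universe)
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(directory, 2) != 0) {
    abort_io(sprintf("cannot write to directory '%s'", directory))
  }
  write_sorted_tsv(
    tibble::tibble(organism_code = universe$organism$code,
                   organism_name = universe$organism$name,
                   version_stamp = universe$version_stamp),
    file.path(directory, "manifest.tsv")
  )
  write_sorted_tsv(
    dplyr::arrange(universe$records, .data$pathway_id),
    file.path(directory, "pathway_titles.tsv")
  )
  write_sorted_tsv(
    dplyr::arrange(
      tibble::tibble(from_id = universe$edges$from, to_id = universe$edges$to),
      .data$from_id, .data$to_id),
    file.path(directory, "pathway_links.tsv")
  )
  write_sorted_tsv(
    dplyr::arrange(universe$gene_map, .data$gene_id, .data$pathway_id),
    file.path(directory, "gene_pathways.tsv")
  )
  write_sorted_tsv(
    tibble::tibble(gene_id = sort(universe$known_genes)),
    file.path(directory, "known_genes.tsv")
  )
  invisible(directory)
}

#' Load a pathway universe from a snapshot directory
#'
#' Accepts either the flat-table snapshot layout written by
#' [save_snapshot()] or a directory of KGML `*.xml` files plus a
#' `manifest.tsv`. Link rows `(a,b)` and `(b,a)` collapse to one undirected
#' edge. An edge referencing a pathway absent from the titles table is an
#' error naming the offending row.
#'
#' @param directory Snapshot directory.
#' @return A [pathway_universe()].
#' @export
load_snapshot <- function(directory) {
  if (!dir.exists(directory)) {
    abort_io(sprintf("snapshot directory '%s' does not exist", directory))
  }
  manifest_path <- file.path(directory, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    abort_input("snapshot is missing file: manifest.tsv")
  }
  manifest <- read_snap_tsv(manifest_path,
                            c("organism_code", "organism_name", "version_stamp"))
  if (nrow(manifest) != 1) abort_input("manifest.tsv must have exactly one row")

  kgml_files <- sort(list.files(directory, pattern = "\\.xml$", full.names = TRUE))
  if (!file.exists(file.path(directory, "pathway_links.tsv")) && length(kgml_files) > 0) {
    return(load_snapshot_kgml(kgml_files, manifest))
  }

  missing <- snapshot_files[!file.exists(file.path(directory, snapshot_files))]
  if (length(missing) > 0) {
    abort_input(sprintf("snapshot is missing file(s): %s", paste(missing, collapse = ", ")))
  }
  titles <- read_snap_tsv(file.path(directory, "pathway_titles.tsv"),
                          c("pathway_id", "title"))
  links <- read_snap_tsv(file.path(directory, "pathway_links.tsv"),
                         c("from_id", "to_id"))
  gene_map <- read_snap_tsv(file.path(directory, "gene_pathways.tsv"),
                            c("gene_id", "pathway_id"))
  known_path <- file.path(directory, "known_genes.tsv")
  known <- if (file.exists(known_path)) {
    read_snap_tsv(known_path, "gene_id")$gene_id
  } else {
    character()
  }

  bad <- which(!(links$from_id %in% titles$pathway_id) |
                 !(links$to_id %in% titles$pathway_id))
  if (length(bad) > 0) {
    abort_input(sprintf(
      "pathway_links.tsv row %d references an unknown pathway (%s -- %s)",
      bad[1] + 1L, links$from_id[bad[1]], links$to_id[bad[1]]
    ))
  }

  pathway_universe(
    records = titles,
    links = tibble::tibble(from = links$from_id, to = links$to_id),
    gene_map = gene_map,
    organism_code = manifest$organism_code,
    organism_name = manifest$organism_name,
    known_genes = known,
    version_stamp = manifest$version_stamp
  )
}

load_snapshot_kgml <- function(kgml_files, manifest) {
  parsed <- purrr::map(kgml_files, parse_kgml)
  records <- purrr::map_dfr(parsed, "record")[c("pathway_id", "title")]
  # keep only links among pathways present in the snapshot
  links <- purrr::map_dfr(parsed, function(p) {
    tibble::tibble(from = p$record$pathway_id, to = p$linked_pathways)
  })
  links <- dplyr::filter(links, .data$to %in% records$pathway_id)
  gene_map <- purrr::map_dfr(parsed, function(p) {
    tibble::tibble(gene_id = p$gene_ids, pathway_id = p$record$pathway_id)
  })
  pathway_universe(
    records = records,
    links = links,
    gene_map = gene_map,
    organism_code = manifest$organism_code,
    organism_name = manifest$organism_name,
    version_stamp = manifest$version_stamp
  )
}
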