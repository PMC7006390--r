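#' Read an offline gene-id annotation table
#'
#' The annotation table replaces a live biomaRt lookup: one row per external
#' id, mapping it to an entrez-style numeric id (empty field = no entrez id).
#' Duplicated external ids are an input error.
#'
#' @param path TSV file with columns `external_id`, `entrez_id`.
#' @return Tibble with columns `external_id`, `entrez_id` (`NA` = missing).
#' @export
read_annotation <- function(path) {
  df <- read_snap_tsv(path, c("external_id", "entrez_id"))
  validate_annotation(df)
}

validate_annotation <- function(annotation) {
  annotation <- tibble::as_tibble(annotation)[c("external_id", "entrez_id")]
  annotation$entrez_id <- as.character(annotation$entrez_id)
  annotation$entrez_id[!is.na(annotation$entrez_id) & annotation$entrez_id == ""] <- NA_character_
  if (any(is.na(annotation$external_id) | !nzchar(annotation$external_id))) {
    abort_input("annotation external_id must be non-empty")
  }
  dup <- annotation$external_id[duplicated(annotation$external_id)]
  if (length(dup) > 0) {
    abort_input(sprintf("duplicated external_id(s) in annotation: %s",
                        paste(utils::head(unique(dup), 5), collapse = ", ")))
  }
  bad <- annotation$entrez_id[!is.na(annotation$entrez_id) & !is_entrez_id(annotation$entrez_id)]
  if (length(bad) > 0) {
    abort_input(sprintf("entrez ids must be numeric text; offending: %s",
                        paste(utils::head(unique(bad), 5), collapse = ", ")))
  }
  annotation
}

#' Map a candidate gene list to entrez ids through an offline annotation
#'
#' Every input gene ends up exactly once in the result, either kept (with its
#' entrez id) or dropped with a reason: `"no_entrez_id"` (present in the
#' annotation but with no entrez id) or `"not_in_annotation"`. Matching is
#' case-sensitive and preserves input order. Duplicated input ids are
#' collapsed to their first occurrence with a warning; distinct external ids
#' mapping to the same entrez id are kept but noted.
#'
#' @param genes Character vector of external gene ids, or a data frame whose
#'   first column holds them.
#' @param annotation Annotation table as from [read_annotation()].
#' @return A tibble of class `prepared_genes` with columns `external_id`,
#'   `entrez_id` (`NA` when dropped), `status` (`"kept"`, `"no_entrez_id"`,
#'   `"not_in_annotation"`). Helpers [kept_genes()] and [dropped_genes()]
#'   select the two sides of the partition.
#' @export
#' @examples
#' ann <- data.frame(external_id = c("TP53", "BRCA2", "LOC1"),
#'                   entrez_id = c("7157", "675", NA))
#' prepare_gene_list(c("TP53", "LOC1", "XYZ"), ann)
prepare_gene_list <- function(genes, annotation) {
  if (is.data.frame(genes)) genes <- genes[[1]]
  genes <- as.character(genes)
  if (length(genes) == 0) abort_input("empty input gene list")
  annotation <- validate_annotation(annotation)

  n_dup <- sum(duplicated(genes))
  if (n_dup > 0) {
    warning(sprintf("input gene list: %d duplicated id(s) collapsed to first occurrence", n_dup),
            call. = FALSE)
    genes <- genes[!duplicated(genes)]
  }

  out <- dplyr::left_join(
    tibble::tibble(external_id = genes),
    dplyr::mutate(annotation, .in_ann = TRUE),
    by = "external_id"
  )
  out$status <- dplyr::case_when(
    is.na(out$.in_ann) ~ "not_in_annotation",
    is.na(out$entrez_id) ~ "no_entrez_id",
    TRUE ~ "kept"
  )
  out$.in_ann <- NULL

  kept <- out[out$status == "kept", ]
  shared <- kept$entrez_id[duplicated(kept$entrez_id)]
  if (length(shared) > 0) {
    message(sprintf(
      "prepare_gene_list: %d external id(s) share an entrez id with another input gene (%s); duplicates are deduplicated downstream",
      sum(kept$entrez_id %in% shared) , paste(unique(shared), collapse = ", ")
    ))
  }
  structure(out, class = c("prepared_genes", class(tibble::tibble())))
}

#' @rdname prepare_gene_list
#' @param x A `prepared_genes` tibble.
#' @export
kept_genes <- function(x) {
  tibble::as_tibble(x)[x$status == "kept", c("external_id", "entrez_id")]
}

#' @rdname prepare_gene_list
#' @export
dropped_genes <- function(x) {
  d <- tibble::as_tibble(x)[x$status != "kept", c("external_id", "status")]
  dplyr::rename(d, reason = "status")
}

# accept a prepared_genes object, a two-column (external, entrez) frame, or a
# bare vector of entrez ids (identity annotation)
as_prepared_genes <- function(genes) {
  if (inherits(genes, "prepared_genes")) return(genes)
  if (is.data.frame(genes) && all(c("external_id", "entrez_id") %in% names(genes))) {
    out <- tibble::as_tibble(genes)[c("external_id", "entrez_id")]
    out$status <- ifelse(is.na(out$entrez_id), "no_entrez_id", "kept")
    return(structure(out, class = c("prepared_genes", class(tibble::tibble()))))
  }
  ids <- as.character(if (is.data.frame(genes)) genes[[1]] else genes)
  structure(
    tibble::tibble(external_id = ids, entrez_id = ids, status = "kept"),
    class = c("prepared_genes", class(tibble::tibble()))
  )
}

validate_deg_values <- function(fold_change, p_value, external_id) {
  bad_fc <- which(!is.finite(fold_change) | fold_change == 0)
  if (length(bad_fc) > 0) {
    abort_input(sprintf(
      "fold_change must be finite and non-zero; offending row %d (%s)",
      bad_fc[1], external_id[bad_fc[1]]
    ))
  }
  bad_p <- which(!is.finite(p_value) | p_value < 0 | p_value > 1)
  if (length(bad_p) > 0) {
    abort_input(sprintf(
      "p_value must lie in [0,1]; offending row %d (%s, p = %s)",
      bad_p[1], external_id[bad_p[1]], format(p_value[bad_p[1]])
    ))
  }
  invisible(TRUE)
}

#' Map an expression gene list (DEG table) to entrez ids
#'
#' Same partition contract as [prepare_gene_list()]; fold changes and
#' p-values are carried through unchanged. Fold changes are signed
#' (log-fold-change style: sign encodes up/downregulation); ratio-style input
#' (all positive, < 1 = downregulated) can be converted with
#' `log_transform = TRUE`, which applies log2.
#'
#' @param rows Data frame with columns `external_id`, `fold_change`,
#'   `p_value`.
#' @param annotation Annotation table as from [read_annotation()].
#' @param log_transform Apply `log2()` to ratio-style fold changes.
#' @return A list with `degs` (tibble `gene_id`, `external_id`,
#'   `fold_change`, `p_value` — the mapped DEG table) and `dropped` (tibble
#'   `external_id`, `reason`).
#' @export
prepare_expression_list <- function(rows, annotation, log_transform = FALSE) {
  rows <- tibble::as_tibble(rows)[c("external_id", "fold_change", "p_value")]
  if (nrow(rows) == 0) abort_input("empty expression gene list")
  rows$fold_change <- as.numeric(rows$fold_change)
  rows$p_value <- as.numeric(rows$p_value)
  if (log_transform) {
    if (any(rows$fold_change <= 0, na.rm = TRUE)) {
      abort_input("log_transform requires strictly positive ratio-style fold changes")
    }
    rows$fold_change <- log2(rows$fold_change)
  }
  validate_deg_values(rows$fold_change, rows$p_value, rows$external_id)

  prep <- prepare_gene_list(rows$external_id, annotation)
  merged <- dplyr::inner_join(rows, kept_genes(prep), by = "external_id")
  degs <- tibble::tibble(
    gene_id = merged$entrez_id,
    external_id = merged$external_id,
    fold_change = merged$fold_change,
    p_value = merged$p_value
  )
  dup <- duplicated(degs$gene_id)
  if (any(dup)) {
    message(sprintf("prepare_expression_list: %d row(s) collapsed onto an already-mapped entrez id",
                    sum(dup)))
    degs <- degs[!dup, ]
  }
  list(degs = degs, dropped = dropped_genes(prep))
}
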