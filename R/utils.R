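# internal validation helpers shared across modules

abort_input <- function(msg, class = "pathlevels_input_error") {
  rlang::abort(msg, class = c(class, "pathlevels_error"))
}

abort_io <- function(msg) {
  rlang::abort(msg, class = c("pathlevels_io_error", "pathlevels_error"))
}

is_pathway_id <- function(x) {
  grepl("^[a-z]{2,4}[0-9]{5}$", x)
}

is_organism_code <- function(x) {
  length(x) == 1L && grepl("^[a-z]{2,4}$", x)
}

is_entrez_id <- function(x) {
  grepl("^[0-9]+$", x)
}

pathway_prefix <- function(ids) sub("[0-9]{5}$", "", ids)
pathway_suffix <- function(ids) stringr::str_sub(ids, -5L)

#' Normalize pathway identifiers to an organism prefix
#'
#' Reference ("map"-prefixed) identifiers are rewritten to the organism prefix
#' of the universe under analysis, so that `map04940` and `hsa04940` name the
#' same pathway. Identifiers already carrying the organism prefix pass through;
#' any other prefix is an error.
#'
#' @param ids Character vector of pathway identifiers
#'   (`<prefix><5 digits>`, prefix `"map"` or an organism code).
#' @param organism_code Target organism code (2--4 lowercase letters).
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_pathway_ids(c("map04940", "hsa00010"), "hsa")
normalize_pathway_ids <- function(ids, organism_code) {
  stopifnot(is.character(ids))
  if (!is_organism_code(organism_code)) {
    abort_input(sprintf("invalid organism code: '%s'", organism_code))
  }
  bad <- ids[!is_pathway_id(ids)]
  if (length(bad) > 0) {
    abort_input(sprintf(
      "malformed pathway id(s): %s (expected <prefix><5 digits>)",
      paste(unique(bad), collapse = ", ")
    ))
  }
  pref <- pathway_prefix(ids)
  foreign <- ids[pref != "map" & pref != organism_code]
  if (length(foreign) > 0) {
    abort_input(sprintf(
      "pathway id(s) with a foreign organism prefix: %s (universe organism is '%s')",
      paste(unique(foreign), collapse = ", "), organism_code
    ))
  }
  ifelse(pref == "map", paste0(organism_code, pathway_suffix(ids)), ids)
}

# sort a two-column edge tibble into canonical undirected form:
# from < to lexicographically, no self loops, no duplicates, sorted rows
canonicalize_edges <- function(from, to) {
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  a <- pmin(from, to)
  b <- pmax(from, to)
  dplyr::distinct(dplyr::arrange(tibble::tibble(from = a, to = b), from, to))
}

`%||%` <- rlang::`%||%`
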