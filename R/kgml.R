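#' Parse a KGML pathway document
#'
#' Reads a single KGML (KEGG Markup Language) XML document and extracts the
#' pathway record, its linked pathways (`entry` elements of type `"map"`),
#' and its member genes (`entry` elements of type `"gene"`). `path:` prefixes
#' are stripped from map entry names and organism prefixes (e.g. `hsa:`) from
#' gene entry names; duplicates collapse; a self-link (the pathway naming
#' itself) is dropped since it carries no crosstalk information. Entry types
#' other than `map` and `gene` (compounds, orthologs, groups, ...) are
#' skipped and counted.
#'
#' @param x KGML XML as a single string, or a path to a KGML file.
#' @return A list with elements `record` (tibble: `pathway_id`, `title`,
#'   `organism`), `linked_pathways` (character), `gene_ids` (character), and
#'   `skipped` (named integer count of skipped entry types).
#' @export
#' @examples
#' u <- generate_universe(fixture_spec(seed = 1))$universe
#' doc <- write_kgml(u, u$records$pathway_id[1])
#' parse_kgml(doc)$record
parse_kgml <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      abort_io(sprintf("malformed KGML document: %s", conditionMessage(e)))
    }
  )
  root <- xml2::xml_name(doc)
  if (root != "pathway") {
    abort_input(sprintf("malformed KGML: root element is <%s>, expected <pathway>", root))
  }
  name <- xml2::xml_attr(doc, "name")
  org <- xml2::xml_attr(doc, "org")
  title <- xml2::xml_attr(doc, "title")
  if (is.na(name) || is.na(org)) {
    abort_input("malformed KGML: <pathway> element lacks a name/org attribute")
  }
  own_id <- sub("^path:", "", name)
  if (!is_pathway_id(own_id)) {
    abort_input(sprintf("malformed KGML: pathway name '%s' is not a pathway id", name))
  }
  if (is.na(title) || !nzchar(title)) title <- own_id

  entries <- xml2::xml_find_all(doc, "./entry")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")
  if (any(is.na(types)) || any(is.na(names_attr))) {
    abort_input("malformed KGML: <entry> element lacks a type/name attribute")
  }

  # an entry's name attribute may hold several space-separated identifiers
  split_names <- function(v) unlist(strsplit(v, "[[:space:]]+"))

  linked <- split_names(names_attr[types == "map"])
  linked <- unique(sub("^path:", "", linked))
  linked <- setdiff(linked[is_pathway_id(linked)], own_id)

  genes <- split_names(names_attr[types == "gene"])
  genes <- unique(sub("^[a-z]{2,4}:", "", genes))

  skipped_types <- types[!types %in% c("map", "gene")]
  skipped <- table(skipped_types)
  skipped <- stats::setNames(as.integer(skipped), names(skipped))
  if (length(skipped) > 0) {
    message(sprintf(
      "parse_kgml: skipped %d entr%s of type(s) %s in %s",
      sum(skipped), if (sum(skipped) == 1) "y" else "ies",
      paste(names(skipped), collapse = ", "), own_id
    ))
  }

  list(
    record = tibble::tibble(pathway_id = own_id, title = title, organism = org),
    linked_pathways = sort(linked),
    gene_ids = sort(genes),
    skipped = skipped
  )
}

#' Write one pathway of a universe as a KGML document
#'
#' Emits a minimal KGML XML document for a pathway: its neighbors in the link
#' graph become `map`-type entries and its annotated genes become `gene`-type
#' entries. Output is deterministic (sorted entries) and round-trips through
#' [parse_kgml()].
#'
#' @param universe A [pathway_universe()].
#' @param pathway_id Pathway to export.
#' @param path Optional file path; when given the XML is written there.
#' @return The XML text (invisibly when `path` is given).
#' @export
write_kgml <- function(universe, pathway_id, path = NULL) {
  assert_universe(universe)
  p <- normalize_pathway_ids(pathway_id, universe$organism$code)
  rec <- universe$records[universe$records$pathway_id == p, ]
  if (nrow(rec) == 0) abort_input(sprintf("pathway '%s' not in universe", p))

  nbr <- universe_neighbors(universe, p)
  genes <- sort(universe$gene_map$gene_id[universe$gene_map$pathway_id == p])
  org <- universe$organism$code

  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  i <- 0L
  entry <- function(name, type) {
    i <<- i + 1L
    sprintf('  <entry id="%d" name="%s" type="%s"/>', i, esc(name), type)
  }
  lines <- c(
    '<?xml version="1.0"?>',
    sprintf('<pathway name="path:%s" org="%s" number="%s" title="%s">',
            p, org, pathway_suffix(p), esc(rec$title)),
    vapply(nbr, function(m) entry(paste0("path:", m), "map"), character(1)),
    vapply(genes, function(g) entry(paste0(org, ":", g), "gene"), character(1)),
    "</pathway>"
  )
  xml <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(xml, path, sep = "")
    return(invisible(xml))
  }
  xml
}
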