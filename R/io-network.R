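# Network export: SIF plus node- and edge-attribute tables, the substrate
# for Cytoscape-style visualization of the drug-target graph.

#' Export a drug-target network
#'
#' Writes three files: `<prefix>.sif` (one interaction per line,
#' `source <TAB> relation <TAB> target`, relations `inhibits`/`activates`/
#' `other`), `<prefix>_nodes.tsv` (node attributes: type drug/gene,
#' expression direction, role, pathway multiplicity, best evidence tier per
#' source) and `<prefix>_edges.tsv` (edge attributes including the
#' `prioritized` flag and its rationale). The SIF file carries no header
#' (per the format); the attribute tables do, so an empty network yields an
#' empty SIF and two header-only TSVs. Output row order is deterministic.
#'
#' @param network A `drug_target_network` (see [build_network()]).
#' @param path_prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_network <- function(network, path_prefix) {
  if (!inherits(network, "drug_target_network")) {
    stop_fs("network must be a drug_target_network")
  }
  edges <- dplyr::arrange(network$edges, .data$drug, .data$gene, .data$source, .data$tier)
  nodes <- dplyr::arrange(network$nodes, .data$type, .data$node)
  sif_path <- paste0(path_prefix, ".sif")
  node_path <- paste0(path_prefix, "_nodes.tsv")
  edge_path <- paste0(path_prefix, "_edges.tsv")
  readr::write_lines(
    sprintf("%s\t%s\t%s", edges$drug, edges$interaction, edges$gene), sif_path)
  readr::write_tsv(nodes, node_path, na = "NA", progress = FALSE)
  readr::write_tsv(edges, edge_path, na = "NA", progress = FALSE)
  invisible(c(sif = sif_path, nodes = node_path, edges = edge_path))
}

#' Re-import an exported drug-target network
#'
#' Reads the node and edge attribute tables written by [write_network()] and
#' reconstructs the `drug_target_network` object (the SIF file is redundant
#' with the edge table and is not consulted).
#'
#' @param path_prefix Prefix used at export time.
#' @return A `drug_target_network`.
#' @export
read_network <- function(path_prefix) {
  nodes <- readr::read_tsv(paste0(path_prefix, "_nodes.tsv"),
                           col_types = readr::cols(
                             meta_pathway_count = readr::col_integer(),
                             .default = readr::col_character()),
                           na = "NA", progress = FALSE)
  edges <- readr::read_tsv(paste0(path_prefix, "_edges.tsv"),
                           col_types = readr::cols(
                             prioritized = readr::col_logical(),
                             .default = readr::col_character()),
                           na = "NA", progress = FALSE)
  new_drug_target_network(nodes, edges)
}

new_drug_target_network <- function(nodes, edges) {
  missing_ep <- setdiff(c(edges$drug, edges$gene), nodes$node)
  if (length(missing_ep) > 0) {
    stop_fs("edge endpoint(s) absent from node table: %s",
            paste(missing_ep, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges), class = "drug_target_network")
}

#' @export
print.drug_target_network <- function(x, ...) {
  cat("<drug_target_network> ", sum(x$nodes$type == "drug"), " drugs, ",
      sum(x$nodes$type == "gene"), " genes, ", nrow(x$edges), " edges (",
      sum(x$edges$prioritized), " prioritized)\n", sep = "")
  invisible(x)
}
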