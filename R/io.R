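#' Read and write edge and role tables
#'
#' Edge tables are TSV with header `source target edge_class sign evidence`;
#' role tables are TSV with header `id role conserved module_label`. Missing
#' optional columns are tolerated on read.
#'
#' @param path File path.
#' @return `read_edge_table()` and `read_node_roles()` return tibbles.
#' @export
read_edge_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_edge_table
#' @param edges,roles Data frames to write.
#' @export
write_edge_table <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}

#' @rdname read_edge_table
#' @export
read_node_roles <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if ("conserved" %in% names(df)) df$conserved <- as.logical(df$conserved)
  df
}

#' @rdname read_edge_table
#' @export
write_node_roles <- function(roles, path) {
  readr::write_tsv(roles, path)
  invisible(path)
}

#' Export a regulatory network to TSV, SIF or GraphML
#'
#' TSV export writes the edge table at `path` and the node table alongside it
#' (suffix `.nodes.tsv`); both are restored losslessly by
#' [import_network()]. GraphML (Cytoscape-loadable) carries roles and edge
#' classes as attributes and also round-trips. SIF
#' (`source edge_class target`) is write-only: it cannot represent isolated
#' nodes or node attributes.
#'
#' @param network A `regulatory_network`.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "regulatory_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(network$edges[, c("source", "target", "edge_class",
                                       "sign", "evidence")], path)
    readr::write_tsv(network$nodes, .nodes_path(path))
  } else if (format == "sif") {
    sif <- network$edges[, c("source", "edge_class", "target")]
    readr::write_tsv(sif, path, col_names = FALSE)
  } else {
    g <- as_igraph(network, drop_self_loops = FALSE)
    # igraph cannot serialise NA character attributes to GraphML
    igraph::V(g)$module_label <- ifelse(is.na(igraph::V(g)$module_label), "",
                                        igraph::V(g)$module_label)
    igraph::E(g)$evidence <- ifelse(is.na(igraph::E(g)$evidence), "",
                                    igraph::E(g)$evidence)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.nodes_path <- function(path) sub("(\\.tsv)?$", ".nodes.tsv", path)

#' Import a regulatory network written by [export_network()]
#'
#' @param path File path (for TSV, the edge-table path; the node table is
#'   looked up alongside).
#' @param format One of `"tsv"`, `"graphml"`.
#' @return A `regulatory_network`.
#' @export
import_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- read_edge_table(path)
    nodes <- read_node_roles(.nodes_path(path))
    return(regulatory_network(nodes, edges))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::tibble(
    id = igraph::V(g)$name,
    role = igraph::V(g)$role,
    conserved = as.logical(igraph::V(g)$conserved),
    module_label = dplyr::na_if(igraph::V(g)$module_label, "")
  )
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(source = el$from, target = el$to,
                          edge_class = el$edge_class, sign = el$sign,
                          evidence = dplyr::na_if(el$evidence, ""))
  regulatory_network(nodes, edges)
}
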