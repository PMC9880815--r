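#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

NODE_ROLES <- c("core_tf", "tf", "mirna", "target_gene")
EDGE_CLASSES <- c("TTI", "TMI", "MTI")
EDGE_SIGNS <- c("activating", "repressing", "unknown")

# Role compatibility of each edge class. TMIs and TTIs emanate from TFs;
# MTIs emanate from miRNAs; TTIs never point at a miRNA locus.
.edge_source_roles <- list(
  TTI = c("tf", "core_tf"),
  TMI = c("tf", "core_tf"),
  MTI = "mirna"
)
.edge_target_roles <- list(
  TTI = c("tf", "core_tf", "target_gene"),
  TMI = "mirna",
  MTI = c("tf", "core_tf", "target_gene")
)
# Role inferred for an endpoint that is absent from the role table. Where the
# class constraint leaves a choice the least specific role is used (tf for
# regulator slots, target_gene for regulated slots); core_tf status always has
# to come from the role table.
.inferred_source_role <- c(TTI = "tf", TMI = "tf", MTI = "mirna")
.inferred_target_role <- c(TTI = "target_gene", TMI = "mirna", MTI = "target_gene")

#' Construct a typed regulatory network
#'
#' A `regulatory_network` holds a node table (gene/miRNA identities and roles)
#' and a directed typed edge table covering the three interaction classes:
#' TF–target (TTI), TF–miRNA (TMI) and miRNA–target (MTI). Self-loops are
#' retained in the edge store but flagged, and are excluded from degree-based
#' statistics and from the motif census.
#'
#' @param nodes Data frame with columns `id`, `role` (one of `core_tf`, `tf`,
#'   `mirna`, `target_gene`) and optionally `conserved` (logical, meaningful
#'   for miRNAs only) and `module_label`.
#' @param edges Data frame with columns `source`, `target`, `edge_class` (one
#'   of `TTI`, `TMI`, `MTI`) and optionally `sign` (`activating`,
#'   `repressing`, `unknown`) and `evidence`.
#' @return An object of class `regulatory_network`: a list with tibbles
#'   `nodes` and `edges` (the latter gains a `self_loop` flag).
#' @export
#' @examples
#' nodes <- data.frame(id = c("TF1", "miR1", "G1"),
#'                     role = c("tf", "mirna", "target_gene"))
#' edges <- data.frame(source = c("TF1", "miR1"), target = c("miR1", "G1"),
#'                     edge_class = c("TMI", "MTI"))
#' net <- regulatory_network(nodes, edges)
#' glance(net)
regulatory_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!all(c("id", "role") %in% names(nodes))) {
    stop("`nodes` needs columns `id` and `role`", call. = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad_role)) {
    stop("unknown node roles: ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  if (!"conserved" %in% names(nodes)) nodes$conserved <- FALSE
  nodes$conserved <- !is.na(nodes$conserved) & as.logical(nodes$conserved)
  nodes$conserved[nodes$role != "mirna"] <- FALSE
  if (!"module_label" %in% names(nodes)) nodes$module_label <- NA_character_
  nodes <- nodes[, c("id", "role", "conserved", "module_label")]

  if (nrow(edges) == 0) {
    edges <- tibble::tibble(source = character(), target = character(),
                            edge_class = character(), sign = character(),
                            evidence = character(), self_loop = logical())
  } else {
    if (!all(c("source", "target", "edge_class") %in% names(edges))) {
      stop("`edges` needs columns `source`, `target`, `edge_class`", call. = FALSE)
    }
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    bad_class <- setdiff(unique(edges$edge_class), EDGE_CLASSES)
    if (length(bad_class)) {
      stop("unknown edge classes: ", paste(bad_class, collapse = ", "),
           call. = FALSE)
    }
    if (!"sign" %in% names(edges)) edges$sign <- "unknown"
    edges$sign[is.na(edges$sign)] <- "unknown"
    bad_sign <- setdiff(unique(edges$sign), EDGE_SIGNS)
    if (length(bad_sign)) {
      stop("unknown edge signs: ", paste(bad_sign, collapse = ", "), call. = FALSE)
    }
    if (!"evidence" %in% names(edges)) edges$evidence <- NA_character_
    edges <- dplyr::distinct(edges, .data$source, .data$target,
                             .data$edge_class, .keep_all = TRUE)
    missing <- setdiff(union(edges$source, edges$target), nodes$id)
    if (length(missing)) {
      stop("edge endpoints absent from node table: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    role_of <- stats::setNames(nodes$role, nodes$id)
    .check_edge_roles(edges, role_of)
    edges$self_loop <- edges$source == edges$target
    edges <- edges[, c("source", "target", "edge_class", "sign", "evidence",
                       "self_loop")]
  }
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

.check_edge_roles <- function(edges, role_of) {
  src_ok <- mapply(function(s, cl) role_of[[s]] %in% .edge_source_roles[[cl]],
                   edges$source, edges$edge_class)
  tgt_ok <- mapply(function(t, cl) role_of[[t]] %in% .edge_target_roles[[cl]],
                   edges$target, edges$edge_class)
  bad <- which(!(src_ok & tgt_ok))
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf(
      "role-incompatible edge at row %d: %s (%s) -%s-> %s (%s)",
      b, edges$source[b], role_of[[edges$source[b]]], edges$edge_class[b],
      edges$target[b], role_of[[edges$target[b]]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble the integrated network from the three interaction classes
#'
#' Integrates MTI, TMI and TTI edge tables into one deduplicated typed
#' network. The node set is the union of all edge endpoints; roles are taken
#' from `node_roles` where available and otherwise inferred from the edge
#' class constraints (an MTI source must be a miRNA, a TMI target must be a
#' miRNA, regulator slots default to `tf`, regulated slots to `target_gene`).
#' Endpoints whose inferred roles conflict across edges raise an error.
#'
#' @param mti_edges,tmi_edges,tti_edges Data frames with columns
#'   `source`, `target` and optionally `sign`, `evidence`. The `edge_class`
#'   column, if present, is overridden by the argument slot.
#' @param node_roles Optional data frame with columns `id`, `role` and
#'   optionally `conserved`, `module_label`.
#' @return A `regulatory_network`. The assembly report (node counts by role,
#'   edge counts by class) is attached as attribute `"assembly"` and shown by
#'   `print()`; `glance()` returns the same counts.
#' @export
assemble_network <- function(mti_edges = NULL, tmi_edges = NULL,
                             tti_edges = NULL, node_roles = NULL) {
  stamp <- function(df, cl) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df <- tibble::as_tibble(df)
    df$edge_class <- cl
    df
  }
  edges <- dplyr::bind_rows(stamp(mti_edges, "MTI"), stamp(tmi_edges, "TMI"),
                            stamp(tti_edges, "TTI"))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(source = character(), target = character(),
                            edge_class = character())
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges <- dplyr::distinct(edges, .data$source, .data$target,
                           .data$edge_class, .keep_all = TRUE)

  known <- if (is.null(node_roles)) {
    tibble::tibble(id = character(), role = character())
  } else {
    tibble::as_tibble(node_roles)
  }
  inferred <- dplyr::bind_rows(
    tibble::tibble(id = edges$source,
                   role = unname(.inferred_source_role[edges$edge_class])),
    tibble::tibble(id = edges$target,
                   role = unname(.inferred_target_role[edges$edge_class]))
  )
  inferred <- dplyr::distinct(inferred[!inferred$id %in% known$id, ])
  if (nrow(inferred)) {
    amb <- inferred$id[duplicated(inferred$id)]
    if (length(amb)) {
      stop("ambiguous role for endpoints absent from `node_roles`: ",
           paste(unique(amb), collapse = ", "), call. = FALSE)
    }
  }
  nodes <- dplyr::bind_rows(known, inferred)
  nodes <- nodes[nodes$id %in% union(edges$source, edges$target), , drop = FALSE]
  net <- regulatory_network(nodes, edges)
  attr(net, "assembly") <- list(
    nodes_by_role = dplyr::count(net$nodes, .data$role, name = "n"),
    edges_by_class = dplyr::count(net$edges, .data$edge_class, name = "n")
  )
  net
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network>\n")
  cat(sprintf("  %d nodes, %d edges (%d self-loops flagged)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$self_loop)))
  rr <- table(factor(x$nodes$role, levels = NODE_ROLES))
  cat("  roles: ", paste(sprintf("%s=%d", names(rr), rr), collapse = ", "), "\n")
  ee <- table(factor(x$edges$edge_class, levels = EDGE_CLASSES))
  cat("  edges: ", paste(sprintf("%s=%d", names(ee), ee), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.regulatory_network <- function(x, ...) {
  roles <- stats::setNames(x$nodes$role, x$nodes$id)
  out <- x$edges
  out$source_role <- unname(roles[out$source])
  out$target_role <- unname(roles[out$target])
  out
}

#' @exportS3Method generics::glance
glance.regulatory_network <- function(x, ...) {
  rr <- table(factor(x$nodes$role, levels = NODE_ROLES))
  ee <- table(factor(x$edges$edge_class, levels = EDGE_CLASSES))
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_core_tf = as.integer(rr[["core_tf"]]), n_tf = as.integer(rr[["tf"]]),
    n_mirna = as.integer(rr[["mirna"]]),
    n_target_gene = as.integer(rr[["target_gene"]]),
    n_tti = as.integer(ee[["TTI"]]), n_tmi = as.integer(ee[["TMI"]]),
    n_mti = as.integer(ee[["MTI"]]),
    n_self_loops = sum(x$edges$self_loop)
  )
}

#' Induce a subnetwork on a set of node ids
#'
#' @param network A `regulatory_network`.
#' @param keep Character vector of node ids to retain.
#' @return A `regulatory_network` containing only the retained nodes and the
#'   edges whose both endpoints are retained.
#' @export
induce_subnetwork <- function(network, keep) {
  stopifnot(inherits(network, "regulatory_network"))
  keep <- intersect(network$nodes$id, keep)
  nodes <- network$nodes[network$nodes$id %in% keep, , drop = FALSE]
  edges <- network$edges[network$edges$source %in% keep &
                           network$edges$target %in% keep, , drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' Convert a regulatory network to an igraph object
#'
#' Node roles and edge classes are carried as vertex/edge attributes.
#'
#' @param network A `regulatory_network`.
#' @param drop_self_loops Drop flagged self-loops (default `TRUE`, matching
#'   their exclusion from topology and motif statistics).
#' @return A directed [igraph::igraph] graph.
#' @export
as_igraph <- function(network, drop_self_loops = TRUE) {
  stopifnot(inherits(network, "regulatory_network"))
  edges <- network$edges
  if (drop_self_loops && nrow(edges)) edges <- edges[!edges$self_loop, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = as.data.frame(edges[, c("source", "target", "edge_class", "sign",
                                "evidence")]),
    directed = TRUE,
    vertices = as.data.frame(network$nodes)
  )
}
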