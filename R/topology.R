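#' Per-node degree profile and out/total (O/T) ratios
#'
#' Computes in-degree, out-degree, total degree and the O/T ratio (out-degree
#' over total degree) for every node, ignoring flagged self-loops. Because
#' every directed edge contributes one out-degree and one in-degree, the
#' network-level O/T ratio (sum of out-degrees over sum of total degrees) is
#' exactly 0.5 for any network with at least one edge.
#'
#' @param network A `regulatory_network`.
#' @param subset Optional character vector of node ids to restrict the
#'   returned rows (degrees are still computed on the full network).
#' @return A tibble with columns `id`, `role`, `d_in`, `d_out`, `degree` and
#'   `ot_ratio` (`NA` for isolated nodes, which are excluded from averages).
#'   Attributes: `network_ot` (0.5 whenever edges exist), `mean_ot` (mean of
#'   the per-node ratios over the returned rows).
#' @export
degree_profile <- function(network, subset = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  edges <- network$edges[!network$edges$self_loop, , drop = FALSE]
  d_out <- table(factor(edges$source, levels = network$nodes$id))
  d_in <- table(factor(edges$target, levels = network$nodes$id))
  prof <- tibble::tibble(
    id = network$nodes$id,
    role = network$nodes$role,
    d_in = as.integer(d_in),
    d_out = as.integer(d_out)
  )
  prof$degree <- prof$d_in + prof$d_out
  prof$ot_ratio <- ifelse(prof$degree > 0, prof$d_out / prof$degree, NA_real_)
  net_ot <- if (sum(prof$d_out) > 0) sum(prof$d_out) / sum(prof$degree) else NA_real_
  if (!is.null(subset)) {
    bad <- setdiff(subset, network$nodes$id)
    if (length(bad)) stop("subset ids not in network: ",
                          paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    prof <- prof[prof$id %in% subset, , drop = FALSE]
  }
  attr(prof, "network_ot") <- net_ot
  attr(prof, "mean_ot") <- mean(prof$ot_ratio, na.rm = TRUE)
  prof
}

#' Mean connectivity of a network or node subset
#'
#' Defined as the mean over nodes of total degree divided by two, so that the
#' whole-network value equals edge count over node count (self-loops
#' excluded). A network of 2096 nodes and 20,282 edges therefore has mean
#' connectivity 9.68. The `raw_degree` variant reports the plain mean total
#' degree (twice the default), since the comparable per-subset statistic is
#' not uniquely determined by the |E|/|N| identity.
#'
#' @param network A `regulatory_network` with at least one node.
#' @param subset Optional nonempty character vector of node ids.
#' @param method `"half_degree"` (default, mean degree / 2) or `"raw_degree"`.
#' @return A single nonnegative number.
#' @export
mean_connectivity <- function(network, subset = NULL,
                              method = c("half_degree", "raw_degree")) {
  method <- match.arg(method)
  if (nrow(network$nodes) == 0) stop("empty network", call. = FALSE)
  if (!is.null(subset) && length(subset) == 0) stop("empty subset", call. = FALSE)
  prof <- degree_profile(network, subset)
  m <- mean(prof$degree)
  if (method == "half_degree") m / 2 else m
}

.local_cc <- function(g_undirected) {
  cc <- igraph::transitivity(g_undirected, type = "local", isolates = "zero")
  # nodes with < 2 neighbours have no neighbour pair; report CC = 0
  cc[is.na(cc)] <- 0
  cc
}

#' Global and per-node topology metrics
#'
#' Clustering coefficients are computed on the undirected simple projection
#' (parallel and antiparallel edges collapsed); betweenness and closeness on
#' the directed graph; the shortest-path-length histogram over reachable
#' ordered node pairs; and the degree-distribution power-law exponent by
#' least squares on the log-log degree histogram (zero-count bins dropped).
#' Closeness of node v is (number of nodes reachable from v) / (sum of
#' directed distances to them), `NA` when nothing is reachable.
#'
#' @param network A `regulatory_network` with at least 2 nodes.
#' @return A `topology_summary`: list with `node_metrics` (per-node tibble:
#'   degrees, O/T, `cc`, `betweenness`, `closeness`), `network` (one-row
#'   tibble: `cc_a`, `mean_connectivity`, `network_ot`, `powerlaw_exponent`,
#'   `n_unreachable_pairs`) and `path_lengths` (tibble `length`, `n`).
#' @export
topology_metrics <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  if (nrow(network$nodes) < 2) stop("need at least 2 nodes", call. = FALSE)
  g <- as_igraph(network)
  gu <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  prof <- degree_profile(network)
  prof$cc <- unname(.local_cc(gu)[match(prof$id, igraph::V(gu)$name)])
  btw <- igraph::betweenness(g, directed = TRUE)
  prof$betweenness <- unname(btw[match(prof$id, names(btw))])
  dmat <- igraph::distances(g, mode = "out")
  diag(dmat) <- Inf
  reached <- rowSums(is.finite(dmat))
  dsum <- apply(dmat, 1, function(r) sum(r[is.finite(r)]))
  clo <- ifelse(reached > 0, reached / dsum, NA_real_)
  prof$closeness <- unname(clo[match(prof$id, rownames(dmat))])

  finite <- dmat[is.finite(dmat)]
  path_lengths <- if (length(finite)) {
    tb <- table(finite)
    tibble::tibble(length = as.integer(names(tb)), n = as.integer(tb))
  } else {
    tibble::tibble(length = integer(), n = integer())
  }
  n_unreach <- sum(!is.finite(dmat)) - nrow(dmat) # exclude the diagonal

  deg <- prof$degree[prof$degree > 0]
  pl_exp <- NA_real_
  if (length(unique(deg)) >= 2) {
    tb <- table(deg)
    fit <- stats::lm(log10(as.numeric(tb)) ~ log10(as.numeric(names(tb))))
    pl_exp <- -unname(stats::coef(fit)[2])
  }
  out <- list(
    node_metrics = prof,
    network = tibble::tibble(
      n_nodes = nrow(network$nodes),
      n_edges = sum(!network$edges$self_loop),
      cc_a = mean(prof$cc),
      mean_connectivity = mean(prof$degree) / 2,
      network_ot = attr(prof, "network_ot"),
      powerlaw_exponent = pl_exp,
      n_unreachable_pairs = n_unreach
    ),
    path_lengths = path_lengths
  )
  class(out) <- "topology_summary"
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("<topology_summary>\n")
  print(x$network)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.topology_summary <- function(x, ...) x$node_metrics

#' @exportS3Method generics::glance
glance.topology_summary <- function(x, ...) x$network

#' Impact of node removal on network topology
#'
#' Recomputes the topology metrics on the induced subgraph of the remaining
#' nodes and reports before/after values with deltas for the network-level
#' statistics and for the mean per-node betweenness, closeness and clustering
#' coefficient. No significance claim is attached to the deltas.
#'
#' @param network A `regulatory_network`.
#' @param removed Character vector of node ids to remove (must be a strict
#'   subset of the node set).
#' @return A `removal_impact`: list with the two `topology_summary` objects
#'   (`before`, `after`) and a `deltas` tibble (`metric`, `before`, `after`,
#'   `delta`).
#' @export
node_removal_impact <- function(network, removed) {
  stopifnot(inherits(network, "regulatory_network"))
  bad <- setdiff(removed, network$nodes$id)
  if (length(bad)) stop("removed ids not in network: ",
                        paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  keep <- setdiff(network$nodes$id, removed)
  if (length(keep) < 2) stop("removal leaves fewer than 2 nodes", call. = FALSE)
  before <- topology_metrics(network)
  after <- topology_metrics(induce_subnetwork(network, keep))
  summarize_one <- function(ts) {
    nm <- ts$node_metrics
    c(cc_a = ts$network$cc_a,
      mean_connectivity = ts$network$mean_connectivity,
      mean_betweenness = mean(nm$betweenness),
      mean_closeness = mean(nm$closeness, na.rm = TRUE))
  }
  b <- summarize_one(before); a <- summarize_one(after)
  out <- list(before = before, after = after,
              deltas = tibble::tibble(metric = names(b), before = unname(b),
                                      after = unname(a), delta = unname(a - b)))
  class(out) <- "removal_impact"
  out
}

#' @export
print.removal_impact <- function(x, ...) {
  cat("<removal_impact>\n")
  print(x$deltas)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.removal_impact <- function(x, ...) x$deltas
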