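#' Classify hub nodes by degree and clustering coefficient
#'
#' In hubs have in-degree strictly greater than `in_threshold`; out hubs have
#' out-degree strictly greater than `out_threshold`. Party/date hub
#' candidates have out-degree strictly greater than `party_out_threshold`
#' and clustering coefficient strictly greater than the network-average
#' clustering coefficient CC_a (computed once on the full network). The
#' party/date split itself needs functional annotation; see
#' [partition_hubs()].
#'
#' @param network A `regulatory_network`.
#' @param roles Node roles to report (default miRNA nodes, the hub class of
#'   interest; use `NODE_ROLES` internally for all).
#' @param in_threshold,out_threshold,party_out_threshold Degree thresholds
#'   (defaults 10, 10, 5).
#' @return Tibble `id`, `role`, `d_in`, `d_out`, `cc`, `is_in_hub`,
#'   `is_out_hub`, `hub_candidate`; attribute `cc_a`.
#' @export
classify_hubs <- function(network, roles = "mirna", in_threshold = 10,
                          out_threshold = 10, party_out_threshold = 5) {
  stopifnot(inherits(network, "regulatory_network"))
  prof <- degree_profile(network)
  gu <- igraph::as_undirected(igraph::simplify(as_igraph(network)),
                              mode = "collapse")
  cc <- unname(.local_cc(gu)[match(prof$id, igraph::V(gu)$name)])
  cc_a <- mean(cc)
  out <- tibble::tibble(
    id = prof$id, role = prof$role, d_in = prof$d_in, d_out = prof$d_out,
    cc = cc,
    is_in_hub = prof$d_in > in_threshold,
    is_out_hub = prof$d_out > out_threshold,
    hub_candidate = prof$d_out > party_out_threshold & cc > cc_a
  )
  out <- out[out$role %in% roles, , drop = FALSE]
  attr(out, "cc_a") <- cc_a
  out
}

# Mean pairwise Jaccard index among a list of GO term sets.
.mean_pairwise_jaccard <- function(sets) {
  k <- length(sets)
  if (k < 2) return(NA_real_)
  pairs <- utils::combn(k, 2)
  js <- apply(pairs, 2, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  })
  mean(js)
}

#' Partition hub candidates into party and date hubs by GO-term similarity
#'
#' For each hub candidate the GO similarity is the mean pairwise Jaccard
#' index over the GO term sets of its annotated regulatory targets
#' (out-neighbours); party hubs act within a module (similar annotations,
#' similarity at or above the threshold), date hubs bridge modules
#' (dissimilar annotations). Hubs with fewer than 2 annotated targets are
#' unclassifiable. This similarity rule stands in for manual curation of
#' target GO terms; the threshold is exposed.
#'
#' @param hubs Output of [classify_hubs()].
#' @param network The same `regulatory_network`.
#' @param go Data frame mapping `gene` to `go_terms` (comma-separated string
#'   or list column of character vectors). Genes with empty term sets are
#'   excluded from the averaging and counted.
#' @param threshold Similarity at or above which a candidate is a party hub
#'   (default 0.3).
#' @return `hubs` with `go_similarity`, `n_annotated_targets` and
#'   `hub_type` (`party`, `date`, `unclassifiable` or `none`) added.
#' @export
partition_hubs <- function(hubs, network, go, threshold = 0.3) {
  go <- tibble::as_tibble(go)
  stopifnot(all(c("gene", "go_terms") %in% names(go)))
  term_sets <- if (is.list(go$go_terms)) go$go_terms else
    strsplit(as.character(go$go_terms), ",\\s*")
  term_sets <- lapply(term_sets, function(x) x[nzchar(x)])
  names(term_sets) <- go$gene
  edges <- network$edges[!network$edges$self_loop, , drop = FALSE]
  res <- purrr::map(hubs$id, function(h) {
    tg <- unique(edges$target[edges$source == h])
    sets <- term_sets[intersect(tg, names(term_sets))]
    sets <- sets[lengths(sets) > 0]
    tibble::tibble(go_similarity = .mean_pairwise_jaccard(sets),
                   n_annotated_targets = length(sets))
  })
  out <- dplyr::bind_cols(hubs, dplyr::bind_rows(res))
  out$hub_type <- dplyr::case_when(
    !out$hub_candidate ~ "none",
    out$n_annotated_targets < 2 ~ "unclassifiable",
    out$go_similarity >= threshold ~ "party",
    TRUE ~ "date"
  )
  attr(out, "cc_a") <- attr(hubs, "cc_a")
  attr(out, "threshold") <- threshold
  out
}

#' Topological generalization of a hub's output feed-forward loops
#'
#' Counts the FFL instances in which the node sits as the intermediate (Y)
#' node, together with the numbers of distinct input (X) and output (Z)
#' nodes among them — the input (`i`) and output (`o`) generalization
#' degrees of the fan of loops around the hub.
#'
#' @param census A `motif_census`.
#' @param hub_ids Character vector of node ids.
#' @return Tibble `id`, `n_output_ffls`, `i_generalization`,
#'   `o_generalization`.
#' @export
count_generalization <- function(census, hub_ids) {
  stopifnot(inherits(census, "motif_census"))
  ffl <- census$ffl
  res <- purrr::map(hub_ids, function(h) {
    sub <- ffl[ffl$y == h, , drop = FALSE]
    tibble::tibble(id = h, n_output_ffls = nrow(sub),
                   i_generalization = dplyr::n_distinct(sub$x),
                   o_generalization = dplyr::n_distinct(sub$z))
  })
  dplyr::bind_rows(res)
}

#' Extract the TF-miRNA core network
#'
#' The induced subnetwork on TF (including core TF) and miRNA nodes,
#' dropping the downstream target-gene layer; the substrate for the
#' hierarchical layer decomposition.
#'
#' @param network A `regulatory_network`.
#' @return A `regulatory_network`; `glance()` reports its composition.
#' @export
extract_core <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  keep <- network$nodes$id[network$nodes$role %in% c("tf", "core_tf", "mirna")]
  core <- induce_subnetwork(network, keep)
  if (nrow(core$nodes) == 0) warning("core network is empty")
  core
}

#' Assign hierarchical layers to core-network nodes
#'
#' Nodes with clustering coefficient strictly greater than the core-network
#' average CC_a form the middle layer. Remaining nodes with out-degree at
#' least `degree_threshold` and in-degree below it are the top layer
#' (out-heavy regulators); those with in-degree at least the threshold and
#' out-degree below it, the bottom layer. Nodes matching neither degree
#' sub-rule (both degrees below, or both at/above, the threshold) default to
#' the bottom layer, making the partition exhaustive and disjoint. CC ties
#' with CC_a fall to the non-middle branch.
#'
#' @param core A `regulatory_network` (typically from [extract_core()]).
#' @param degree_threshold Degree cut (default 10; "no less than" is
#'   inclusive).
#' @return A tibble of class `layer_assignment`: `id`, `role`, `cc`, `d_in`,
#'   `d_out`, `layer` (factor top/middle/bottom); attributes `cc_a` and
#'   `degree_threshold`.
#' @export
assign_layers <- function(core, degree_threshold = 10) {
  stopifnot(inherits(core, "regulatory_network"))
  prof <- degree_profile(core)
  gu <- igraph::as_undirected(igraph::simplify(as_igraph(core)),
                              mode = "collapse")
  cc <- unname(.local_cc(gu)[match(prof$id, igraph::V(gu)$name)])
  cc_a <- mean(cc)
  layer <- ifelse(cc > cc_a, "middle",
           ifelse(prof$d_out >= degree_threshold & prof$d_in < degree_threshold,
                  "top", "bottom"))
  out <- tibble::tibble(id = prof$id, role = prof$role, cc = cc,
                        d_in = prof$d_in, d_out = prof$d_out,
                        layer = factor(layer, levels = c("top", "middle",
                                                         "bottom")))
  attr(out, "cc_a") <- cc_a
  attr(out, "degree_threshold") <- degree_threshold
  class(out) <- c("layer_assignment", class(out))
  out
}

#' @exportS3Method generics::glance
glance.layer_assignment <- function(x, ...) {
  tb <- table(x$layer)
  tibble::tibble(n_nodes = nrow(x), n_top = as.integer(tb[["top"]]),
                 n_middle = as.integer(tb[["middle"]]),
                 n_bottom = as.integer(tb[["bottom"]]),
                 cc_a = attr(x, "cc_a"))
}

#' Layer shares
#'
#' @param layers A `layer_assignment`.
#' @return Tibble `layer`, `n`, `share`.
#' @export
layer_share <- function(layers) {
  tb <- table(layers$layer)
  tibble::tibble(layer = names(tb), n = as.integer(tb),
                 share = as.integer(tb) / nrow(layers))
}

#' Layer orientation of feed-forward loops
#'
#' For each FFL compares the layer of the input node X with that of the
#' output node Z under the ordering top > middle > bottom, tallying
#' higher/equal/lower; reported for all instances and for the
#' miRNA-containing subset. Instances with an unassigned X or Z are skipped
#' and counted in attribute `n_skipped`.
#'
#' @param census A `motif_census` computed on the (core) network.
#' @param layers A `layer_assignment` for the same network.
#' @return Tibble `subset` (`all`/`mirna`), `comparison`
#'   (`higher`/`equal`/`lower`), `n`, `fraction`.
#' @export
layer_orientation <- function(census, layers) {
  stopifnot(inherits(census, "motif_census"),
            inherits(layers, "layer_assignment"))
  rank <- c(top = 3, middle = 2, bottom = 1)
  lv <- stats::setNames(rank[as.character(layers$layer)], layers$id)
  ffl <- census$ffl
  rx <- unname(lv[ffl$x]); rz <- unname(lv[ffl$z])
  ok <- !is.na(rx) & !is.na(rz)
  cmp <- ifelse(rx[ok] > rz[ok], "higher", ifelse(rx[ok] == rz[ok], "equal",
                                                  "lower"))
  tally <- function(cmp, label) {
    n <- c(higher = sum(cmp == "higher"), equal = sum(cmp == "equal"),
           lower = sum(cmp == "lower"))
    tibble::tibble(subset = label, comparison = names(n), n = unname(n),
                   fraction = if (sum(n) > 0) unname(n) / sum(n) else NA_real_)
  }
  out <- dplyr::bind_rows(
    tally(cmp, "all"),
    tally(cmp[ffl$contains_mirna[ok]], "mirna"))
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Functional modules reached by a node
#'
#' A date-hub crosstalk measure: the set of functional modules a node
#' touches, either through incoming TMI edges from module-labelled TFs or
#' through outgoing MTI edges into genes regulated (TTI) by module-labelled
#' TFs. Neighbours without a module label are ignored and counted.
#'
#' @param network A `regulatory_network`.
#' @param modules Data frame `tf`, `module` labelling (core) TFs.
#' @param node Node id.
#' @return Tibble `module`, `via` (`tmi_in`/`mti_out`), distinct rows;
#'   attributes `n_modules`, `n_unlabelled`.
#' @export
module_connectivity <- function(network, modules, node) {
  stopifnot(inherits(network, "regulatory_network"))
  modules <- tibble::as_tibble(modules)
  lab <- stats::setNames(modules$module, modules$tf)
  e <- network$edges[!network$edges$self_loop, , drop = FALSE]
  up_tfs <- e$source[e$target == node & e$edge_class == "TMI"]
  up_mod <- unname(lab[up_tfs])
  out_genes <- e$target[e$source == node & e$edge_class == "MTI"]
  # module membership of a gene: regulated by a labelled TF via TTI
  tti <- e[e$edge_class == "TTI" & e$target %in% out_genes, , drop = FALSE]
  down_mod <- unname(lab[tti$source])
  res <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(module = up_mod[!is.na(up_mod)], via = "tmi_in"),
    tibble::tibble(module = down_mod[!is.na(down_mod)], via = "mti_out")))
  attr(res, "n_modules") <- dplyr::n_distinct(res$module)
  attr(res, "n_unlabelled") <- sum(is.na(up_mod)) + sum(is.na(down_mod))
  res
}

#' Share of core-network TFs that are miRNA targets
#'
#' Fraction of TF nodes (tf or core_tf) in the network that receive at
#' least one MTI edge.
#'
#' @param network A `regulatory_network` (typically the core network, with
#'   MTI edges from the full network supplied via `mti_edges` if they point
#'   at TFs retained in the core).
#' @param mti_edges Optional edge table to use instead of the network's own
#'   MTI edges.
#' @return Tibble `n_tf`, `n_targeted`, `share`.
#' @export
core_target_share <- function(network, mti_edges = NULL) {
  tfs <- network$nodes$id[network$nodes$role %in% c("tf", "core_tf")]
  e <- if (is.null(mti_edges)) {
    network$edges[network$edges$edge_class == "MTI", , drop = FALSE]
  } else {
    tibble::as_tibble(mti_edges)
  }
  targeted <- intersect(tfs, unique(e$target))
  tibble::tibble(n_tf = length(tfs), n_targeted = length(targeted),
                 share = length(targeted) / length(tfs))
}

#' Overlay expression summaries and group tests on node sets
#'
#' Summarises relative expression (e.g., mutant vs wild-type log-ratios) per
#' group and condition and runs a two-group test per condition for every
#' pair of groups (rank-sum/Mann-Whitney by default). Group pairs in which
#' either group has fewer than 3 measured members in a condition get the
#' summary only, no test.
#'
#' @param groups Named list of character vectors of gene ids (disjoint
#'   groups, e.g., targets vs non-targets, or per layer).
#' @param expression Data frame `gene`, `condition`, `rel_level`.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return An `expression_overlay`: list with `summary` (tibble `group`,
#'   `condition`, `n`, `mean`, `median`, `q25`, `q75`) and `tests` (tibble
#'   `condition`, `group1`, `group2`, `statistic`, `p_value`).
#' @export
expression_overlay <- function(groups, expression, test = c("wilcox", "t")) {
  test <- match.arg(test)
  expression <- tibble::as_tibble(expression)
  stopifnot(all(c("gene", "condition", "rel_level") %in% names(expression)))
  gdf <- dplyr::bind_rows(purrr::imap(groups, function(ids, nm)
    tibble::tibble(gene = ids, group = nm)))
  if (anyDuplicated(gdf$gene)) stop("groups must be disjoint", call. = FALSE)
  df <- dplyr::inner_join(expression, gdf, by = "gene")
  summary <- df %>%
    dplyr::group_by(.data$group, .data$condition) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$rel_level),
                     median = stats::median(.data$rel_level),
                     q25 = stats::quantile(.data$rel_level, 0.25),
                     q75 = stats::quantile(.data$rel_level, 0.75),
                     .groups = "drop")
  gnames <- names(groups)
  pairs <- if (length(gnames) >= 2) utils::combn(gnames, 2) else
    matrix(character(), nrow = 2)
  tests <- purrr::map(unique(df$condition), function(cond) {
    purrr::map(seq_len(ncol(pairs)), function(j) {
      x <- df$rel_level[df$condition == cond & df$group == pairs[1, j]]
      y <- df$rel_level[df$condition == cond & df$group == pairs[2, j]]
      if (length(x) < 3 || length(y) < 3) {
        return(tibble::tibble(condition = cond, group1 = pairs[1, j],
                              group2 = pairs[2, j], statistic = NA_real_,
                              p_value = NA_real_))
      }
      ht <- if (test == "wilcox") stats::wilcox.test(x, y, exact = FALSE)
            else stats::t.test(x, y)
      tibble::tibble(condition = cond, group1 = pairs[1, j],
                     group2 = pairs[2, j], statistic = unname(ht$statistic),
                     p_value = ht$p.value)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  out <- list(summary = summary, tests = tests, test = test)
  class(out) <- "expression_overlay"
  out
}

#' @export
print.expression_overlay <- function(x, ...) {
  cat(sprintf("<expression_overlay test=%s>\n", x$test))
  print(x$tests)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.expression_overlay <- function(x, ...) x$tests

#' @exportS3Method generics::glance
glance.expression_overlay <- function(x, ...) {
  tibble::tibble(n_groups = dplyr::n_distinct(x$summary$group),
                 n_conditions = dplyr::n_distinct(x$summary$condition),
                 test = x$test)
}
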