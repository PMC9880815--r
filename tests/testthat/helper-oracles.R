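# Brute-force oracles, deliberately independent of the package internals.

# adjacency matrix from a regulatory_network (self-loops dropped)
adj_matrix <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  e <- net$edges[!net$edges$self_loop, , drop = FALSE]
  m[cbind(match(e$source, ids), match(e$target, ids))] <- TRUE
  m
}

# exhaustive ordered-triple census
oracle_census <- function(adj, mode = "induced") {
  n <- nrow(adj)
  ffl <- 0L
  if (n >= 3) {
    for (x in 1:n) for (y in 1:n) for (z in 1:n) {
      if (x == y || y == z || x == z) next
      if (adj[x, y] && adj[y, z] && adj[x, z]) {
        extra <- adj[y, x] || adj[z, y] || adj[z, x]
        if (mode == "match" || !extra) ffl <- ffl + 1L
      }
    }
  }
  fbl <- 0L
  if (n >= 3) {
    for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
      cyc1 <- adj[a, b] && adj[b, cc] && adj[cc, a]
      cyc2 <- adj[a, cc] && adj[cc, b] && adj[b, a]
      if (!(cyc1 || cyc2)) next
      if (mode == "induced") {
        ne <- adj[a, b] + adj[b, a] + adj[b, cc] + adj[cc, b] +
          adj[a, cc] + adj[cc, a]
        if (ne == 3) fbl <- fbl + 1L
      } else {
        fbl <- fbl + 1L
      }
    }
  }
  c(FFL = ffl, FBL = fbl)
}

# Floyd-Warshall all-pairs shortest paths on the directed graph
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# number of distinct shortest paths per ordered pair, by dynamic programming
# over the Floyd-Warshall distances
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  cnt <- matrix(0, n, n)
  diag(cnt) <- 1
  for (s in 1:n) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] & d[s, ] == d[s, t] - 1)
      cnt[s, t] <- sum(cnt[s, preds])
    }
  }
  cnt
}

# directed betweenness via the pair-dependency formula
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  cnt <- oracle_path_counts(adj, d)
  btw <- numeric(n)
  for (v in 1:n) {
    for (s in 1:n) for (t in 1:n) {
      if (s == t || s == v || t == v) next
      if (!is.finite(d[s, t]) || cnt[s, t] == 0) next
      if (d[s, v] + d[v, t] == d[s, t]) {
        btw[v] <- btw[v] + cnt[s, v] * cnt[v, t] / cnt[s, t]
      }
    }
  }
  btw
}

oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  diag(d) <- Inf
  apply(d, 1, function(r) {
    fin <- r[is.finite(r)]
    if (length(fin) == 0) NA_real_ else length(fin) / sum(fin)
  })
}

# local clustering coefficient on the undirected simple projection
oracle_cc <- function(adj) {
  und <- adj | t(adj)
  n <- nrow(adj)
  vapply(1:n, function(v) {
    nb <- which(und[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    pairs <- utils::combn(nb, 2)
    sum(und[cbind(pairs[1, ], pairs[2, ])]) / ncol(pairs)
  }, numeric(1))
}

# random role-free digraph wrapped as a regulatory_network of TFs
random_tf_network <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  g <- expand.grid(s = seq_len(n), t = seq_len(n))
  g <- g[g$s != g$t, , drop = FALSE]
  g <- g[stats::runif(nrow(g)) < p, , drop = FALSE]
  if (nrow(g) == 0) g <- data.frame(s = 1, t = 2)
  edges <- data.frame(source = ids[g$s], target = ids[g$t],
                      edge_class = "TTI")
  regulatory_network(data.frame(id = ids, role = "tf"), edges)
}

# random typed network with miRNAs and targets (role-consistent edges)
random_typed_network <- function(n_tf = 6, n_mir = 5, n_tgt = 8, p = 0.15,
                                 seed = 1) {
  set.seed(seed)
  tf <- sprintf("TF%02d", seq_len(n_tf))
  mir <- sprintf("MI%02d", seq_len(n_mir))
  tgt <- sprintf("TG%02d", seq_len(n_tgt))
  nodes <- data.frame(
    id = c(tf, mir, tgt),
    role = c(rep("tf", n_tf), rep("mirna", n_mir), rep("target_gene", n_tgt)))
  pick <- function(ss, tt) {
    g <- expand.grid(s = ss, t = tt, stringsAsFactors = FALSE)
    g <- g[g$s != g$t, , drop = FALSE]
    g[stats::runif(nrow(g)) < p, , drop = FALSE]
  }
  tti <- pick(tf, c(tf, tgt)); tmi <- pick(tf, mir); mti <- pick(mir, c(tf, tgt))
  edges <- rbind(
    if (nrow(tti)) data.frame(source = tti$s, target = tti$t, edge_class = "TTI"),
    if (nrow(tmi)) data.frame(source = tmi$s, target = tmi$t, edge_class = "TMI"),
    if (nrow(mti)) data.frame(source = mti$s, target = mti$t, edge_class = "MTI"))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = tf[1], target = mir[1], edge_class = "TMI")
  }
  regulatory_network(nodes, edges)
}
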