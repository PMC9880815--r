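tri_net <- function(edges) {
  ids <- unique(c(edges$source, edges$target))
  regulatory_network(data.frame(id = ids, role = "tf"), edges)
}

test_that("census identifies the canonical FFL and FBL patterns", {
  ffl <- tri_net(data.frame(source = c("X", "Y", "X"),
                            target = c("Y", "Z", "Z"), edge_class = "TTI"))
  for (mode in c("induced", "match")) {
    cen <- census_triads(ffl, mode = mode)
    expect_equal(cen$counts$n[cen$counts$motif == "FFL"], 1L)
    expect_equal(cen$counts$n[cen$counts$motif == "FBL"], 0L)
    expect_equal(unlist(cen$ffl[1, c("x", "y", "z")], use.names = FALSE),
                 c("X", "Y", "Z"))
  }
  fbl <- tri_net(data.frame(source = c("A", "B", "C"),
                            target = c("B", "C", "A"), edge_class = "TTI"))
  for (mode in c("induced", "match")) {
    cen <- census_triads(fbl, mode = mode)
    expect_equal(cen$counts$n[cen$counts$motif == "FFL"], 0L)
    expect_equal(cen$counts$n[cen$counts$motif == "FBL"], 1L)
  }
})

test_that("census equals exhaustive ordered-triple enumeration", {
  set.seed(77)
  specs <- data.frame(n = sample(5:15, 60, replace = TRUE),
                      p = runif(60, 0.05, 0.3))
  for (i in seq_len(nrow(specs))) {
    net <- random_tf_network(specs$n[i], specs$p[i], seed = 7000 + i)
    adj <- adj_matrix(net)
    for (mode in c("induced", "match")) {
      cen <- census_triads(net, mode = mode)
      oracle <- oracle_census(adj, mode)
      expect_equal(cen$counts$n[cen$counts$motif == "FFL"],
                   unname(oracle["FFL"]),
                   info = paste("FFL", mode, "case", i))
      expect_equal(cen$counts$n[cen$counts$motif == "FBL"],
                   unname(oracle["FBL"]),
                   info = paste("FBL", mode, "case", i))
    }
  }
})

test_that("match-mode counts dominate induced counts and igraph agrees", {
  for (s in 1:10) {
    net <- random_tf_network(12, 0.25, seed = 300 + s)
    ind <- census_triads(net, "induced")$counts
    mat <- census_triads(net, "match")$counts
    expect_true(all(mat$n >= ind$n))
    # cross-check the induced census against igraph's triad classification:
    # class 030T is the transitive (FFL) triad, 030C the cyclic (FBL) triad
    tc <- igraph::triad_census(as_igraph(net))
    expect_equal(ind$n[ind$motif == "FFL"], tc[9])
    expect_equal(ind$n[ind$motif == "FBL"], tc[10])
  }
})

test_that("census flags miRNA positions within FFL instances", {
  nodes <- data.frame(id = c("T1", "M1", "G1"),
                      role = c("tf", "mirna", "target_gene"))
  net <- regulatory_network(nodes, data.frame(
    source = c("T1", "M1", "T1"), target = c("M1", "G1", "G1"),
    edge_class = c("TMI", "MTI", "TTI")))
  cen <- census_triads(net)
  expect_true(cen$ffl$contains_mirna)
  expect_equal(cen$ffl$mirna_position, "Y")
  stats <- mirna_position_stats(cen)
  expect_equal(stats$n[stats$position == "Y"], 1L)
  expect_equal(stats$proportion[stats$position == "Y"], 1)
})

test_that("position proportions reproduce the published Y-node share", {
  # 19,615 FFLs of which 6976 contain a miRNA and 5334 place it at Y
  n_y <- 5334; n_x <- 6976 - 5334; n_none <- 19615 - 6976
  mk <- function(n, prefix, role_y) {
    tibble::tibble(
      x = sprintf("%sX%05d", prefix, 1:n),
      y = sprintf("%sY%05d", prefix, 1:n),
      z = sprintf("%sZ%05d", prefix, 1:n))
  }
  blocks <- list(y = mk(n_y, "a"), x = mk(n_x, "b"), none = mk(n_none, "c"))
  nodes <- tibble::tibble(
    id = c(unlist(lapply(blocks, function(b) c(b$x, b$y, b$z)))))
  nodes$role <- "tf"
  nodes$role[nodes$id %in% blocks$y$y] <- "mirna"
  nodes$role[nodes$id %in% blocks$x$x] <- "mirna"
  nodes$role[grepl("Z", nodes$id)] <- "target_gene"
  all_ffl <- dplyr::bind_rows(blocks)
  edges <- dplyr::bind_rows(
    tibble::tibble(source = all_ffl$x, target = all_ffl$y,
                   edge_class = ifelse(all_ffl$x %in% blocks$x$x, "MTI",
                                       ifelse(all_ffl$y %in% blocks$y$y,
                                              "TMI", "TTI"))),
    tibble::tibble(source = all_ffl$y, target = all_ffl$z,
                   edge_class = ifelse(all_ffl$y %in% blocks$y$y, "MTI",
                                       "TTI")),
    tibble::tibble(source = all_ffl$x, target = all_ffl$z,
                   edge_class = ifelse(all_ffl$x %in% blocks$x$x, "MTI",
                                       "TTI")))
  net <- regulatory_network(nodes, edges)
  cen <- census_triads(net)
  expect_equal(nrow(cen$ffl), 19615L)
  stats <- mirna_position_stats(cen)
  expect_equal(attr(stats, "n_mirna_ffl"), 6976L)
  # 35.6% of FFLs contain a miRNA; 76.5% of those have it at Y; 27.2% of
  # all FFLs have a miRNA at Y
  expect_equal(round(100 * attr(stats, "n_mirna_ffl") /
                       attr(stats, "n_total_ffl"), 1), 35.6)
  expect_equal(round(100 * stats$proportion[stats$position == "Y"], 1), 76.5)
  expect_equal(round(100 * stats$n[stats$position == "Y"] /
                       attr(stats, "n_total_ffl"), 1), 27.2)
})

test_that("position tallies equal a brute-force scan on typed networks", {
  for (s in 1:5) {
    net <- random_typed_network(p = 0.25, seed = 400 + s)
    cen <- census_triads(net)
    is_mir <- stats::setNames(net$nodes$role == "mirna", net$nodes$id)
    stats <- mirna_position_stats(cen)
    expect_equal(stats$n[stats$position == "X"], sum(is_mir[cen$ffl$x]))
    expect_equal(stats$n[stats$position == "Y"], sum(is_mir[cen$ffl$y]))
    expect_equal(stats$n[stats$position == "Z"], sum(is_mir[cen$ffl$z]))
    expect_equal(attr(stats, "n_mirna_ffl"),
                 sum(is_mir[cen$ffl$x] | is_mir[cen$ffl$y] |
                       is_mir[cen$ffl$z]))
    # sum over positions >= number of miRNA-containing FFLs
    expect_gte(sum(stats$n), attr(stats, "n_mirna_ffl"))
  }
})

test_that("permutation Z-scores are reproducible and preserve graph size", {
  net <- random_typed_network(p = 0.2, seed = 55)
  e1 <- permutation_zscore(net, n_perm = 50, seed = 99)
  e2 <- permutation_zscore(net, n_perm = 50, seed = 99)
  expect_identical(e1$z, e2$z)
  e3 <- permutation_zscore(net, n_perm = 50, seed = 100)
  expect_false(identical(e3$z, e1$z))
  # role-preserving nulls produce only role-compatible edges: verified
  # indirectly by the constraint machinery reusing the class pools; here we
  # check the reported observed counts agree between constraints
  e4 <- permutation_zscore(net, n_perm = 20, seed = 1,
                           constraint = "role_preserving")
  expect_equal(e4$observed, e1$observed)
})

test_that("degenerate nulls give Z = 0 at the mean and Inf off it", {
  # complete digraph on 3 nodes: every permutation is the same graph
  ids <- c("A", "B", "C")
  g <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  g <- g[g$source != g$target, ]
  g$edge_class <- "TTI"
  net <- regulatory_network(data.frame(id = ids, role = "tf"), g)
  enr <- permutation_zscore(net, n_perm = 10, seed = 1)
  expect_equal(enr$null_sd, c(0, 0))
  expect_equal(enr$z[enr$motif == "FFL"], 0)  # 0 observed, 0 in every null
})

test_that("planted FFLs score as enriched, random graphs do not", {
  sim <- simulate_network(sim_config(seed = 5))
  enr <- permutation_zscore(sim$network, n_perm = 100, seed = 5)
  expect_gt(enr$z[enr$motif == "FFL"], 2)
  net <- random_tf_network(30, 0.1, seed = 6)
  enr0 <- permutation_zscore(net, n_perm = 100, seed = 6)
  expect_lt(abs(enr0$z[enr0$motif == "FFL"]), 4)
})

test_that("two-proportion chi-square matches the closed form", {
  got <- proportion_test(10, 100, 20, 200)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  # hand-computed Pearson statistic on random tables
  set.seed(10)
  for (i in 1:20) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    o <- c(k1, n1 - k1, k2, n2 - k2)
    p_pool <- (k1 + k2) / (n1 + n2)
    e <- c(n1 * p_pool, n1 * (1 - p_pool), n2 * p_pool, n2 * (1 - p_pool))
    got <- suppressWarnings(proportion_test(k1, n1, k2, n2))
    expect_equal(got$statistic, sum((o - e)^2 / e), tolerance = 1e-10)
  }
  # miRNA share in nodes vs in FFLs clears the P < 0.001 threshold
  got <- proportion_test(318, 2096, 6976, 19615)
  expect_gt(got$statistic, 10.83)
  expect_lt(got$p_value, 0.001)
  expect_error(proportion_test(0, 10, 0, 20), "zero margin")
})

test_that("coherence follows the sign product of the indirect path", {
  # an activating TTI/TMI input with repressive miRNA arm: coherent when
  # the direct edge is repressing (HY5-type wiring)
  expect_equal(classify_coherence("activating", "repressing", "repressing"),
               "coherent")
  # a repressing input with repressive miRNA arm: indirect + vs direct -
  expect_equal(classify_coherence("repressing", "repressing", "repressing"),
               "incoherent")
  expect_equal(classify_coherence("unknown", "repressing", "repressing"),
               "unclassified")
  expect_equal(classify_coherence("activating", NA, "repressing"),
               "unclassified")
})

test_that("coherence annotation reads signs off the network edges", {
  nodes <- data.frame(id = c("T1", "M1", "G1"),
                      role = c("tf", "mirna", "target_gene"))
  net <- regulatory_network(nodes, data.frame(
    source = c("T1", "M1", "T1"), target = c("M1", "G1", "G1"),
    edge_class = c("TMI", "MTI", "TTI"),
    sign = c("activating", "repressing", "repressing")))
  cen <- annotate_coherence(census_triads(net), net)
  expect_equal(cen$ffl$coherence, "coherent")
  net2 <- regulatory_network(nodes, data.frame(
    source = c("T1", "M1", "T1"), target = c("M1", "G1", "G1"),
    edge_class = c("TMI", "MTI", "TTI"),
    sign = c("repressing", "repressing", "repressing")))
  cen2 <- annotate_coherence(census_triads(net2), net2)
  expect_equal(cen2$ffl$coherence, "incoherent")
})
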