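test_that("hub flags apply strict degree thresholds", {
  # miRNA with in-degree 11: in hub only
  mir <- "M1"
  tfs <- sprintf("T%02d", 1:11)
  nodes <- data.frame(id = c(mir, tfs), role = c("mirna", rep("tf", 11)))
  net <- regulatory_network(nodes, data.frame(
    source = tfs, target = mir, edge_class = "TMI"))
  h <- classify_hubs(net)
  expect_true(h$is_in_hub)
  expect_false(h$is_out_hub)
  # out-degree exactly 5 is NOT enough for party/date candidacy
  tgts <- sprintf("G%02d", 1:5)
  nodes <- data.frame(id = c(mir, tgts),
                      role = c("mirna", rep("target_gene", 5)))
  net <- regulatory_network(nodes, data.frame(
    source = mir, target = tgts, edge_class = "MTI"))
  h <- classify_hubs(net)
  expect_false(h$hub_candidate)
  expect_equal(h$d_out, 5L)
})

test_that("hub flags equal brute-force threshold evaluation", {
  for (s in 1:5) {
    net <- random_typed_network(n_tf = 8, n_mir = 6, n_tgt = 12, p = 0.3,
                                seed = 500 + s)
    h <- classify_hubs(net, roles = c("core_tf", "tf", "mirna",
                                      "target_gene"))
    prof <- degree_profile(net)
    j <- match(h$id, prof$id)
    expect_equal(h$is_in_hub, prof$d_in[j] > 10)
    expect_equal(h$is_out_hub, prof$d_out[j] > 10)
    expect_equal(h$hub_candidate,
                 prof$d_out[j] > 5 & h$cc > attr(h, "cc_a"))
  }
})

test_that("GO similarity is the mean pairwise Jaccard over targets", {
  mir <- "M1"; tgts <- sprintf("G%02d", 1:6); tfs <- sprintf("T%02d", 1:3)
  nodes <- data.frame(id = c(mir, tgts, tfs),
                      role = c("mirna", rep("target_gene", 6), rep("tf", 3)))
  edges <- rbind(
    data.frame(source = mir, target = tgts, edge_class = "MTI"),
    expand.grid(source = tfs, target = tgts,
                stringsAsFactors = FALSE) |>
      dplyr::mutate(edge_class = "TTI"),
    data.frame(source = tfs, target = mir, edge_class = "TMI"))
  net <- regulatory_network(nodes, edges)
  hubs <- classify_hubs(net)
  # identical GO sets: similarity 1 -> party
  go <- data.frame(gene = tgts, go_terms = "GO:1,GO:2")
  ph <- partition_hubs(hubs, net, go)
  expect_equal(ph$go_similarity, 1)
  expect_equal(ph$hub_type, "party")
  # pairwise disjoint sets: similarity 0 -> date
  go <- data.frame(gene = tgts, go_terms = sprintf("GO:%d", 1:6))
  ph <- partition_hubs(hubs, net, go)
  expect_equal(ph$go_similarity, 0)
  expect_equal(ph$hub_type, "date")
  # fewer than 2 annotated targets: unclassifiable
  ph <- partition_hubs(hubs, net, go[1, , drop = FALSE])
  expect_equal(ph$hub_type, "unclassifiable")
  # random annotations match a brute-force pairwise average
  set.seed(20)
  go <- data.frame(gene = tgts, go_terms = vapply(tgts, function(g)
    paste(sample(sprintf("GO:%d", 1:8), 3), collapse = ","), character(1)))
  ph <- partition_hubs(hubs, net, go)
  sets <- strsplit(go$go_terms, ",")
  pr <- utils::combn(6, 2)
  jac <- mean(apply(pr, 2, function(p)
    length(intersect(sets[[p[1]]], sets[[p[2]]])) /
      length(union(sets[[p[1]]], sets[[p[2]]]))))
  expect_equal(ph$go_similarity, jac)
  # permutation-invariant in target order
  ph2 <- partition_hubs(hubs, net, go[sample(6), ])
  expect_equal(ph2$go_similarity, ph$go_similarity)
  expect_true(ph$go_similarity >= 0 && ph$go_similarity <= 1)
})

test_that("generalization counts describe the hub's FFL fan", {
  # one regulator X, two targets, full fan: 2 output FFLs, i = 1, o = 2
  nodes <- data.frame(id = c("X1", "M1", "Z1", "Z2"),
                      role = c("tf", "mirna", "target_gene", "target_gene"))
  net <- regulatory_network(nodes, rbind(
    data.frame(source = "X1", target = "M1", edge_class = "TMI"),
    data.frame(source = "M1", target = c("Z1", "Z2"), edge_class = "MTI"),
    data.frame(source = "X1", target = c("Z1", "Z2"), edge_class = "TTI")))
  cen <- census_triads(net)
  g <- count_generalization(cen, "M1")
  expect_equal(g$n_output_ffls, 2L)
  expect_equal(g$i_generalization, 1L)
  expect_equal(g$o_generalization, 2L)
  # no upstream regulator: all zero
  expect_equal(unlist(count_generalization(cen, "Z1")[, -1],
                      use.names = FALSE), c(0L, 0L, 0L))
  # random typed graph: counts equal a direct scan of the instance list
  net <- random_typed_network(p = 0.3, seed = 31)
  cen <- census_triads(net)
  for (h in sample(net$nodes$id, 5)) {
    g <- count_generalization(cen, h)
    sub <- cen$ffl[cen$ffl$y == h, ]
    expect_equal(g$n_output_ffls, nrow(sub))
    expect_equal(g$i_generalization, length(unique(sub$x)))
    expect_equal(g$o_generalization, length(unique(sub$z)))
  }
})

test_that("core extraction induces on TF and miRNA nodes", {
  net <- random_typed_network(n_tf = 6, n_mir = 5, n_tgt = 10, p = 0.25,
                              seed = 40)
  core <- extract_core(net)
  expect_setequal(core$nodes$role, c("tf", "mirna"))
  keep <- core$nodes$id
  manual <- net$edges[net$edges$source %in% keep &
                        net$edges$target %in% keep, ]
  expect_equal(nrow(core$edges), nrow(manual))
  # no TF/miRNA nodes: empty core
  tonly <- regulatory_network(
    data.frame(id = c("G1", "G2"), role = "target_gene"),
    data.frame(source = character(), target = character(),
               edge_class = character()))
  expect_warning(core0 <- extract_core(tonly), "empty")
  expect_equal(nrow(core0$nodes), 0L)
})

test_that("layer rule boundaries are honoured and the partition is total", {
  lay <- simulate_layered_core(sim_config(seed = 2))
  la <- assign_layers(lay$network)
  # every node assigned exactly one layer
  expect_equal(nrow(la), nrow(lay$network$nodes))
  expect_false(any(is.na(la$layer)))
  # rule equivalence with direct evaluation
  cc_a <- attr(la, "cc_a")
  exp_layer <- ifelse(la$cc > cc_a, "middle",
                      ifelse(la$d_out >= 10 & la$d_in < 10, "top", "bottom"))
  expect_equal(as.character(la$layer), exp_layer)
  # out-degree exactly 10 with low CC is top ("no less than" inclusive)
  top10 <- la[la$d_out == 10 & la$d_in < 10 & la$cc <= cc_a, ]
  if (nrow(top10)) expect_true(all(top10$layer == "top"))
  # high CC wins regardless of degrees
  expect_true(all(la$layer[la$cc > cc_a] == "middle"))
})

test_that("planted layers are recovered exactly", {
  for (s in 1:20) {
    lay <- simulate_layered_core(sim_config(seed = s))
    la <- assign_layers(lay$network)
    expect_equal(as.character(la$layer[match(lay$truth$layers$id, la$id)]),
                 lay$truth$layers$layer, info = paste("seed", s))
  }
})

test_that("layer orientation tallies X vs Z positions", {
  lay <- simulate_layered_core(sim_config(seed = 3))
  la <- assign_layers(lay$network)
  cen <- census_triads(lay$network)
  lo <- layer_orientation(cen, la)
  mir <- lo[lo$subset == "mirna", ]
  # planted loops run top -> bottom: X strictly higher than Z
  expect_equal(mir$fraction[mir$comparison == "higher"], 1)
  # tallies equal a per-instance comparison
  rank <- c(top = 3, middle = 2, bottom = 1)
  lv <- stats::setNames(rank[as.character(la$layer)], la$id)
  cmp <- sign(lv[cen$ffl$x] - lv[cen$ffl$z])
  allr <- lo[lo$subset == "all", ]
  expect_equal(allr$n[allr$comparison == "higher"], sum(cmp > 0))
  expect_equal(allr$n[allr$comparison == "equal"], sum(cmp == 0))
  expect_equal(allr$n[allr$comparison == "lower"], sum(cmp < 0))
})

test_that("module connectivity collects labels from both directions", {
  nodes <- data.frame(
    id = c("M1", "T1", "T2", "T3", "G1", "G2"),
    role = c("mirna", "tf", "tf", "tf", "target_gene", "target_gene"))
  edges <- rbind(
    data.frame(source = c("T1", "T2"), target = "M1", edge_class = "TMI"),
    data.frame(source = "M1", target = c("G1", "G2"), edge_class = "MTI"),
    data.frame(source = "T3", target = "G1", edge_class = "TTI"))
  net <- regulatory_network(nodes, edges)
  modules <- data.frame(tf = c("T1", "T2", "T3"),
                        module = c("light", "hormone", "development"))
  mc <- module_connectivity(net, modules, "M1")
  expect_setequal(mc$module, c("light", "hormone", "development"))
  expect_equal(attr(mc, "n_modules"), 3L)
  # isolated node: empty set
  mc0 <- module_connectivity(net, modules, "G2")
  expect_equal(nrow(mc0), 0L)
  # unlabelled neighbours are ignored and counted
  mc1 <- module_connectivity(net, modules[1, , drop = FALSE], "M1")
  expect_setequal(mc1$module, "light")
  expect_gt(attr(mc1, "n_unlabelled"), 0)
})

test_that("core target share counts TFs with incoming MTIs", {
  tfs <- sprintf("T%03d", 1:249)
  mirs <- sprintf("M%03d", 1:275)
  nodes <- data.frame(id = c(tfs, mirs),
                      role = c(rep("tf", 249), rep("mirna", 275)))
  # 193 of the 249 TFs receive an MTI
  edges <- data.frame(source = mirs[(0:192) %% 275 + 1], target = tfs[1:193],
                      edge_class = "MTI")
  net <- regulatory_network(nodes, edges)
  share <- core_target_share(net)
  expect_equal(share$n_targeted, 193L)
  expect_equal(round(100 * share$share, 1), 77.5)
  expect_equal(nrow(net$nodes), 524L)
})

test_that("expression overlay summarises groups and runs rank-sum tests", {
  set.seed(50)
  expr <- rbind(
    data.frame(gene = sprintf("a%02d", 1:20), condition = "c1",
               rel_level = rnorm(20, 1)),
    data.frame(gene = sprintf("b%02d", 1:20), condition = "c1",
               rel_level = rnorm(20, 0)))
  ov <- expression_overlay(list(A = sprintf("a%02d", 1:20),
                                B = sprintf("b%02d", 1:20)), expr)
  expect_equal(nrow(ov$summary), 2L)
  expect_lt(ov$tests$p_value, 0.05)
  # identical distributions: p near 1 (same values in both groups)
  expr2 <- rbind(
    data.frame(gene = sprintf("a%02d", 1:10), condition = "c1",
               rel_level = 1:10),
    data.frame(gene = sprintf("b%02d", 1:10), condition = "c1",
               rel_level = 1:10))
  ov2 <- expression_overlay(list(A = sprintf("a%02d", 1:10),
                                 B = sprintf("b%02d", 1:10)), expr2)
  expect_gt(ov2$tests$p_value, 0.9)
  # small groups are summarised but not tested
  ov3 <- expression_overlay(list(A = sprintf("a%02d", 1:2),
                                 B = sprintf("b%02d", 1:10)), expr2)
  expect_true(is.na(ov3$tests$p_value))
  # exact rank computation on a tiny example (Mann-Whitney U)
  expr4 <- rbind(
    data.frame(gene = c("x1", "x2", "x3"), condition = "c1",
               rel_level = c(5, 6, 7)),
    data.frame(gene = c("y1", "y2", "y3"), condition = "c1",
               rel_level = c(1, 2, 3)))
  ov4 <- expression_overlay(list(A = c("x1", "x2", "x3"),
                                 B = c("y1", "y2", "y3")), expr4)
  expect_equal(ov4$tests$statistic, 9)  # all x above all y: U = 3 * 3
  expect_error(expression_overlay(list(A = "g1", B = "g1"), expr4),
               "disjoint")
})
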