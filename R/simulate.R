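#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generators: node counts per
#' role, background edge probabilities per edge class, planted structure
#' specs (FFLs, party/date hubs, layered scaffold), a genome spec for the
#' peak-assignment fixtures, a prediction spec for the MTI merge fixtures
#' and an expression spec. Identical config and seed give byte-identical
#' outputs.
#'
#' @param seed Integer seed (single RNG stream per generator run).
#' @param n_core_tf,n_tf,n_mirna,n_target Node counts per role.
#' @param p_tti,p_tmi,p_mti Background Bernoulli edge probabilities per
#'   role-compatible ordered pair (simple digraph, no self-loops).
#' @param n_planted_ffls Number of planted TF -> miRNA -> target FFLs (the
#'   canonical miRNA-as-Y configuration).
#' @param conserved_frac Fraction of miRNAs flagged as conserved.
#' @param party_hub,date_hub Lists `n_targets`, `n_upstream`: planted hub
#'   fan sizes (party targets share one GO pool; date targets get pairwise
#'   disjoint pools and upstream TFs from distinct modules).
#' @param layered List for the layered core scaffold: `n_top`,
#'   `n_middle_cliques`, `clique_size`, `n_bottom`, `n_ffls`, `in_degree`
#'   (bottom in-degree from the top layer) and `p_extra_down` (extra
#'   top->bottom edges).
#' @param genome List: `n_chrom`, `chrom_length`, `n_coding`,
#'   `n_mirna_loci`, `n_peaks`, `frac_in_window`, `spacing` (anchor
#'   spacing, chosen so that binding windows never overlap).
#' @param predictions List: `n_both`, `n_a_only`, `n_b_only`,
#'   `degradome_frac` (fraction of single-program pairs with degradome
#'   support), `n_decoys`, `n_curated`, `n_curated_novel`,
#'   `benchmark_size`.
#' @param expression List: `effect` (log-units added to miRNA targets in
#'   the ago1-like condition only), `noise_sd`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_core_tf = 10, n_tf = 30, n_mirna = 40, n_target = 150,
                       p_tti = 0.01, p_tmi = 0.01, p_mti = 0.01,
                       n_planted_ffls = 30, conserved_frac = 0.4,
                       party_hub = list(n_targets = 10, n_upstream = 4),
                       date_hub = list(n_targets = 8, n_upstream = 4),
                       layered = list(n_top = 12, n_middle_cliques = 2,
                                      clique_size = 4, n_bottom = 60,
                                      n_ffls = 20, in_degree = 10,
                                      p_extra_down = 0),
                       genome = list(n_chrom = 2, chrom_length = 1e6,
                                     n_coding = 30, n_mirna_loci = 10,
                                     n_peaks = 200, frac_in_window = 0.7,
                                     spacing = 10000),
                       predictions = list(n_both = 60, n_a_only = 30,
                                          n_b_only = 30, degradome_frac = 0.5,
                                          n_decoys = 40, n_curated = 15,
                                          n_curated_novel = 10,
                                          benchmark_size = 40),
                       expression = list(effect = 1.0, noise_sd = 0.3)) {
  cfg <- as.list(environment())
  probs <- c(p_tti, p_tmi, p_mti, genome$frac_in_window,
             predictions$degradome_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]",
                                       call. = FALSE)
  structure(cfg, class = "sim_config")
}

.bernoulli_pairs <- function(sources, targets, p) {
  if (p <= 0 || length(sources) == 0 || length(targets) == 0) {
    return(tibble::tibble(source = character(), target = character()))
  }
  grid <- expand.grid(source = sources, target = targets,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
}

#' Simulate a typed regulatory network with planted structures
#'
#' Draws background TTI/TMI/MTI edges as per-class Bernoulli edges honouring
#' the role constraints, then plants (i) `n_planted_ffls` feed-forward loops
#' in the canonical TF -> miRNA -> target configuration (dedicated Y and Z
#' nodes per loop, activating TMI and repressing MTI/TTI signs, making them
#' coherent), (ii) one party hub whose target fan shares a single GO pool
#' and (iii) one date hub whose targets carry pairwise disjoint GO pools and
#' whose upstream TFs belong to distinct functional modules. Both hubs get
#' full FFL fans (every upstream TF also binds every hub target), which
#' gives them the high clustering coefficient hub candidacy requires.
#'
#' @param config A [sim_config()].
#' @param seed Seed override (default `config$seed`).
#' @return List with `network` (a `regulatory_network`), `truth` (list:
#'   `ffls`, `hubs` = tibble `id`, `hub_type`, `modules`) and `go` (tibble
#'   `gene`, `go_terms`).
#' @export
simulate_network <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n_mir_needed <- config$n_planted_ffls + 2
  if (n_mir_needed > config$n_mirna) {
    stop("more planted structures than miRNA nodes", call. = FALSE)
  }
  if (config$n_planted_ffls + config$party_hub$n_targets +
        config$date_hub$n_targets > config$n_target) {
    stop("more planted structures than target nodes", call. = FALSE)
  }
  withr::with_seed(seed, {
    ctf <- sprintf("CTF%02d", seq_len(config$n_core_tf))
    tfs <- sprintf("TF%03d", seq_len(config$n_tf))
    mir <- sprintf("miR%03d", seq_len(config$n_mirna))
    tgt <- sprintf("G%04d", seq_len(config$n_target))
    nodes <- tibble::tibble(
      id = c(ctf, tfs, mir, tgt),
      role = c(rep("core_tf", length(ctf)), rep("tf", length(tfs)),
               rep("mirna", length(mir)), rep("target_gene", length(tgt))),
      conserved = FALSE, module_label = NA_character_)
    nodes$conserved[nodes$role == "mirna"] <-
      stats::runif(length(mir)) < config$conserved_frac

    regs <- c(ctf, tfs)
    bg_tti <- .bernoulli_pairs(regs, c(regs, tgt), config$p_tti)
    bg_tmi <- .bernoulli_pairs(regs, mir, config$p_tmi)
    bg_mti <- .bernoulli_pairs(mir, c(regs, tgt), config$p_mti)
    bg <- dplyr::bind_rows(
      dplyr::mutate(bg_tti, edge_class = "TTI"),
      dplyr::mutate(bg_tmi, edge_class = "TMI"),
      dplyr::mutate(bg_mti, edge_class = "MTI"))
    bg$sign <- "unknown"; bg$evidence <- "background"
    # the planted hubs' adjacency is fully specified by the plant: background
    # edges avoid the two hub miRNAs so their fan, clustering coefficient and
    # GO-similarity are exactly the planted construction
    hub_mirnas <- mir[config$n_planted_ffls + 1:2]
    bg <- bg[!(bg$source %in% hub_mirnas | bg$target %in% hub_mirnas), ,
             drop = FALSE]

    # planted FFLs: X a TF, Y a dedicated miRNA, Z a dedicated target
    k <- config$n_planted_ffls
    fx <- tfs[(seq_len(k) - 1) %% length(tfs) + 1]
    fy <- mir[seq_len(k)]
    fz <- tgt[seq_len(k)]
    ffl_edges <- dplyr::bind_rows(
      tibble::tibble(source = fx, target = fy, edge_class = "TMI",
                     sign = "activating"),
      tibble::tibble(source = fy, target = fz, edge_class = "MTI",
                     sign = "repressing"),
      tibble::tibble(source = fx, target = fz, edge_class = "TTI",
                     sign = "repressing"))
    ffl_edges$evidence <- "planted_ffl"

    # planted hubs with full FFL fans
    hub_edges <- list(); go_rows <- list(); modules <- list()
    next_tgt <- k; next_ctf <- 0
    hub_specs <- list(party = config$party_hub, date = config$date_hub)
    if (config$party_hub$n_upstream + config$date_hub$n_upstream >
          config$n_core_tf) {
      stop("planted hubs need more core TFs than available", call. = FALSE)
    }
    hub_ids <- c(party = mir[k + 1], date = mir[k + 2])
    for (type in names(hub_specs)) {
      spec <- hub_specs[[type]]
      y <- hub_ids[[type]]
      ups <- ctf[next_ctf + seq_len(spec$n_upstream)]
      next_ctf <- next_ctf + spec$n_upstream
      zs <- tgt[next_tgt + seq_len(spec$n_targets)]
      next_tgt <- next_tgt + spec$n_targets
      up_pairs <- utils::combn(ups, 2)
      hub_edges[[type]] <- dplyr::bind_rows(
        tibble::tibble(source = ups, target = y,
                       edge_class = "TMI", sign = "unknown"),
        tibble::tibble(source = y, target = zs, edge_class = "MTI",
                       sign = "repressing"),
        tidyr::expand_grid(source = ups, target = zs) %>%
          dplyr::mutate(edge_class = "TTI", sign = "unknown"),
        # interconnect the upstream regulators so the hub neighbourhood is
        # genuinely clustered (hub candidacy requires CC above average)
        tibble::tibble(source = up_pairs[1, ], target = up_pairs[2, ],
                       edge_class = "TTI", sign = "unknown"))
      if (type == "party") {
        go_rows[[type]] <- tibble::tibble(
          gene = zs, go_terms = "GO:P001,GO:P002,GO:P003")
      } else {
        go_rows[[type]] <- tibble::tibble(
          gene = zs,
          go_terms = vapply(seq_along(zs), function(j)
            paste(sprintf("GO:D%03d", (j - 1) * 3 + 1:3), collapse = ","),
            character(1)))
        modules[[type]] <- tibble::tibble(
          tf = ups, module = sprintf("module_%d", seq_along(ups)))
      }
    }
    hub_edges <- dplyr::bind_rows(hub_edges)
    hub_edges$evidence <- "planted_hub"

    edges <- dplyr::bind_rows(ffl_edges, hub_edges, bg)
    edges <- dplyr::distinct(edges, .data$source, .data$target,
                             .data$edge_class, .keep_all = TRUE)
    mods <- dplyr::bind_rows(modules)
    if (nrow(mods)) {
      nodes$module_label[match(mods$tf, nodes$id)] <- mods$module
    }
    net <- regulatory_network(nodes, edges)
    # background GO annotation for remaining targets
    rest <- setdiff(tgt, unlist(lapply(go_rows, `[[`, "gene")))
    go_bg <- tibble::tibble(
      gene = rest,
      go_terms = unname(vapply(rest, function(g)
        paste(sample(sprintf("GO:B%03d", 1:40), 3), collapse = ","),
        character(1))))
    truth <- list(
      ffls = tibble::tibble(x = fx, y = fy, z = fz),
      hubs = tibble::tibble(id = unname(hub_ids),
                            hub_type = names(hub_ids)),
      modules = mods)
    list(network = net, truth = truth,
         go = dplyr::bind_rows(go_rows$party, go_rows$date, go_bg))
  })
}

#' Simulate a layered TF-miRNA core network with planted hierarchy
#'
#' Builds the canonical layered scaffold: `n_top` out-heavy regulators
#' (each bottom node receives `in_degree` top regulators by round-robin, so
#' top out-degrees are at/above the layer threshold and in-degrees zero),
#' `n_bottom` in-heavy nodes with no outgoing edges, and a middle layer of
#' fully connected TF cliques whose clustering coefficient of 1 exceeds the
#' network average. `n_ffls` feed-forward loops are planted with X drawn
#' from the top layer, Z from the bottom layer and a fresh miRNA Y per loop
#' (whose two neighbours are connected, placing it in the middle layer).
#' Optional extra top->bottom edges are drawn with probability
#' `p_extra_down`; the default 0 keeps the planted layer margins exact.
#'
#' @param config A [sim_config()].
#' @param seed Seed override.
#' @return List with `network` and `truth` (list: `layers` = tibble `id`,
#'   `layer`; `ffls`).
#' @export
simulate_layered_core <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$layered
  if (L$n_ffls > L$n_bottom) stop("more planted FFLs than bottom nodes",
                                  call. = FALSE)
  if (L$in_degree > L$n_top) stop("bottom in-degree exceeds top layer size",
                                  call. = FALSE)
  withr::with_seed(seed, {
    top <- sprintf("TOP%02d", seq_len(L$n_top))
    mid <- sprintf("MID%02d", seq_len(L$n_middle_cliques * L$clique_size))
    bot <- sprintf("BOT%03d", seq_len(L$n_bottom))
    ymir <- sprintf("miRY%02d", seq_len(L$n_ffls))
    nodes <- tibble::tibble(
      id = c(top, mid, bot, ymir),
      role = c(rep("core_tf", length(top)), rep("tf", length(mid)),
               rep("tf", length(bot)), rep("mirna", length(ymir))),
      conserved = FALSE, module_label = NA_character_)

    # round-robin top -> bottom wiring
    down <- dplyr::bind_rows(lapply(seq_along(bot), function(i) {
      js <- ((i - 1) + seq_len(L$in_degree) - 1) %% L$n_top + 1
      tibble::tibble(source = top[js], target = bot[i])
    }))
    extra <- .bernoulli_pairs(top, bot, L$p_extra_down)
    clique <- dplyr::bind_rows(lapply(seq_len(L$n_middle_cliques), function(q) {
      ids <- mid[(q - 1) * L$clique_size + seq_len(L$clique_size)]
      pr <- utils::combn(ids, 2)
      tibble::tibble(source = pr[1, ], target = pr[2, ])
    }))
    tti <- dplyr::bind_rows(down, extra, clique)
    tti$edge_class <- "TTI"

    fx <- top[(seq_len(L$n_ffls) - 1) %% L$n_top + 1]
    fz <- bot[seq_len(L$n_ffls)]
    ffl <- dplyr::bind_rows(
      tibble::tibble(source = fx, target = ymir, edge_class = "TMI"),
      tibble::tibble(source = ymir, target = fz, edge_class = "MTI"),
      tibble::tibble(source = fx, target = fz, edge_class = "TTI"))
    edges <- dplyr::distinct(dplyr::bind_rows(tti, ffl),
                             .data$source, .data$target, .data$edge_class)
    net <- regulatory_network(nodes, edges)
    truth <- list(
      layers = tibble::tibble(
        id = c(top, mid, bot, ymir),
        layer = c(rep("top", length(top)), rep("middle", length(mid)),
                  rep("bottom", length(bot)), rep("middle", length(ymir)))),
      ffls = tibble::tibble(x = fx, y = ymir, z = fz))
    list(network = net, truth = truth)
  })
}

#' Simulate a genome fixture with peaks of known window membership
#'
#' Places coding and miRNA anchors on alternating strands at a fixed spacing
#' chosen so binding windows never overlap, then places the stated fraction
#' of peak midpoints uniformly inside a randomly chosen window and the rest
#' in the gaps between windows (strictly outside all of them).
#'
#' @param config A [sim_config()].
#' @param params Window parameters used to guarantee membership.
#' @param seed Seed override.
#' @return List with `anchors`, `peaks` and `truth` (tibble `peak_id`,
#'   `gene_id`; `NA` gene for planted outside-window peaks).
#' @export
simulate_genome <- function(config = sim_config(), params = window_params(),
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$genome
  span <- max(params$coding_upstream + params$coding_downstream,
              params$mirna_upstream + params$mirna_downstream) + 1
  if (G$spacing < 2 * span) stop("anchor spacing too small for the windows",
                                 call. = FALSE)
  n_anchor <- G$n_coding + G$n_mirna_loci
  per_chrom <- ceiling(n_anchor / G$n_chrom)
  if (G$spacing * (per_chrom + 1) > G$chrom_length) {
    stop("window placement infeasible on these chromosome lengths",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    idx <- seq_len(n_anchor)
    anchors <- tibble::tibble(
      gene_id = c(sprintf("AT%04d", seq_len(G$n_coding)),
                  sprintf("MIR%03d", seq_len(G$n_mirna_loci))),
      chrom = sprintf("Chr%d", (idx - 1) %% G$n_chrom + 1),
      strand = ifelse(idx %% 2 == 0, "-", "+"),
      anchor = (ceiling(idx / G$n_chrom)) * G$spacing,
      gene_class = c(rep("coding", G$n_coding), rep("mirna", G$n_mirna_loci)))
    win <- compute_window(anchors, params)
    n_in <- round(G$n_peaks * G$frac_in_window)
    pick <- sample.int(nrow(win), n_in, replace = TRUE)
    mid_in <- floor(stats::runif(n_in, win$win_start[pick],
                                 win$win_end[pick] + 1))
    # decoys go midway between consecutive anchor slots: >= spacing/2 - span
    # away from every window
    pick_out <- sample.int(nrow(win), G$n_peaks - n_in, replace = TRUE)
    mid_out <- win$anchor[pick_out] + round(G$spacing / 2)
    peaks <- tibble::tibble(
      chrom = c(win$chrom[pick], win$chrom[pick_out]),
      start = c(mid_in, mid_out) - 100,
      end = c(mid_in, mid_out) + 101,
      tf_id = sprintf("CHIPTF%d", (seq_len(G$n_peaks) - 1) %% 5 + 1),
      score = round(stats::runif(G$n_peaks, 10, 100), 2))
    gene_vec <- c(win$gene_id[pick], rep(NA_character_, G$n_peaks - n_in))
    ord <- sample.int(G$n_peaks)
    peaks <- peaks[ord, , drop = FALSE]
    truth <- tibble::tibble(peak_id = seq_len(G$n_peaks),
                            gene_id = gene_vec[ord])
    list(anchors = anchors, peaks = peaks, truth = truth)
  })
}

#' Simulate predictor, degradome, curated and benchmark tables
#'
#' Constructs the two predictor outputs and the degradome-support table so
#' that the intended merge result is known by construction: `n_both` pairs
#' predicted by both programs, single-program pairs of which a fraction
#' carry degradome support (rescued) and the rest do not (decoys), plus
#' extra decoys, a curated list partially novel, and a benchmark drawn from
#' the intended merge result.
#'
#' @param config A [sim_config()].
#' @param seed Seed override.
#' @return List with `pred_a`, `pred_b`, `degradome`, `curated`,
#'   `benchmark` tibbles and `truth` (list: `merged` = intended
#'   [merge_mti()] result pairs, `final_n` = intended [add_validated()]
#'   count).
#' @export
simulate_predictions <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  P <- config$predictions
  withr::with_seed(seed, {
    n_pairs <- P$n_both + P$n_a_only + P$n_b_only + P$n_decoys +
      P$n_curated_novel + 10
    mirnas <- sprintf("miR%03d", 1:60)
    genes <- sprintf("G%04d", 1:400)
    grid_idx <- sample.int(length(mirnas) * length(genes), n_pairs)
    pool <- tibble::tibble(
      mirna_id = mirnas[(grid_idx - 1) %% length(mirnas) + 1],
      gene_id = genes[(grid_idx - 1) %/% length(mirnas) + 1])
    take <- function(n) {
      if (n == 0) return(pool[0, , drop = FALSE])
      out <- pool[seq_len(n), , drop = FALSE]
      pool <<- pool[-seq_len(n), , drop = FALSE]
      out
    }
    both <- take(P$n_both)
    a_only <- take(P$n_a_only)
    b_only <- take(P$n_b_only)
    decoys <- take(P$n_decoys)
    n_supp_a <- round(P$n_a_only * P$degradome_frac)
    n_supp_b <- round(P$n_b_only * P$degradome_frac)
    supp <- dplyr::bind_rows(utils::head(a_only, n_supp_a),
                             utils::head(b_only, n_supp_b))
    merged_truth <- dplyr::bind_rows(both, supp)

    novel <- take(P$n_curated_novel)
    n_cur_known <- max(0, P$n_curated - P$n_curated_novel)
    curated <- dplyr::bind_rows(novel,
                                utils::head(merged_truth, n_cur_known))
    benchmark <- merged_truth[sample.int(nrow(merged_truth),
                                         min(P$benchmark_size,
                                             nrow(merged_truth))), ]
    score <- function(df) dplyr::mutate(df, score = round(stats::runif(
      nrow(df), 0.5, 2.5), 2))
    half <- sample.int(nrow(decoys), floor(nrow(decoys) / 2))
    pred_a <- score(dplyr::bind_rows(both, a_only, decoys[half, ]))
    pred_b <- score(dplyr::bind_rows(both, b_only, decoys[-half, ]))
    degradome <- dplyr::mutate(supp, supported = TRUE,
                               category = sample(c("cat_1", "cat_2", "cat_3"),
                                                 nrow(supp), replace = TRUE))
    list(pred_a = pred_a, pred_b = pred_b, degradome = degradome,
         curated = curated, benchmark = benchmark,
         truth = list(merged = merged_truth,
                      final_n = nrow(merged_truth) + P$n_curated_novel))
  })
}

#' Simulate relative expression with a target-specific ago1-like shift
#'
#' Emulates the comparison of miRNA-pathway mutants to the wild type: miRNA
#' target genes receive a `+effect` log-unit shift in the ago1-like
#' condition only (miRNA action lost, targets de-repressed), while the
#' rdr6-like condition (siRNA pathway) and wild type carry noise only.
#'
#' @param config A [sim_config()].
#' @param network A `regulatory_network` with MTI edges.
#' @param seed Seed override.
#' @return List with `expression` (tibble `gene`, `condition`,
#'   `rel_level`) and `truth` (tibble `gene`, `is_target`).
#' @export
simulate_expression <- function(config = sim_config(), network,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            inherits(network, "regulatory_network"))
  E <- config$expression
  mti <- network$edges[network$edges$edge_class == "MTI", , drop = FALSE]
  if (nrow(mti) == 0) stop("network has no MTI targets", call. = FALSE)
  genes <- network$nodes$id[network$nodes$role != "mirna"]
  is_target <- genes %in% mti$target
  withr::with_seed(seed, {
    conds <- c("wt", "ago1_like", "rdr6_like")
    expr <- tidyr::expand_grid(gene = genes, condition = conds)
    shift <- ifelse(expr$condition == "ago1_like" &
                      expr$gene %in% mti$target, E$effect, 0)
    expr$rel_level <- shift + stats::rnorm(nrow(expr), 0, E$noise_sd)
    list(expression = expr,
         truth = tibble::tibble(gene = genes, is_target = is_target))
  })
}

#' Write the full set of simulated artifacts to a directory
#'
#' Emits role and per-class edge TSVs, GFF3 anchors, BED peaks, prediction
#' and expression TSVs and a ground-truth JSON, all generated from one
#' config and seed.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
simulate_to_dir <- function(config = sim_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_network(config)
  net <- sim$network
  write_node_roles(net$nodes, file.path(outdir, "roles.tsv"))
  for (cl in EDGE_CLASSES) {
    write_edge_table(net$edges[net$edges$edge_class == cl, , drop = FALSE],
                     file.path(outdir, paste0(tolower(cl), "_edges.tsv")))
  }
  gen <- simulate_genome(config)
  write_anchors_gff3(gen$anchors, file.path(outdir, "anchors.gff3"))
  write_peaks_bed(gen$peaks, file.path(outdir, "peaks.bed"))
  pred <- simulate_predictions(config)
  readr::write_tsv(pred$pred_a, file.path(outdir, "pred_a.tsv"))
  readr::write_tsv(pred$pred_b, file.path(outdir, "pred_b.tsv"))
  readr::write_tsv(pred$degradome, file.path(outdir, "degradome.tsv"))
  readr::write_tsv(pred$curated, file.path(outdir, "curated.tsv"))
  readr::write_tsv(pred$benchmark, file.path(outdir, "benchmark.tsv"))
  expr <- simulate_expression(config, net)
  readr::write_tsv(expr$expression, file.path(outdir, "expression.tsv"))
  truth <- list(seed = config$seed, ffls = sim$truth$ffls,
                hubs = sim$truth$hubs, peak_truth = gen$truth,
                merged = pred$truth$merged)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(outdir)
}
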