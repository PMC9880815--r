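# Internal 3-node motif counting on integer edge lists.
#
# `src`/`tgt` are 1-based node indices; self-loops and duplicate (src, tgt)
# pairs are dropped (motifs are defined on the simple digraph of distinct
# directed adjacencies, regardless of how many edge classes connect a pair).
# FFLs are counted per role assignment (X, Y, Z are distinguishable); FBLs
# once per unordered node set. In `induced` mode a triple counts only when
# no extra edges exist among the three nodes.
.count_motifs <- function(n, src, tgt, mode = "induced",
                          want_instances = FALSE) {
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  key <- (src - 1) * n + tgt
  dup <- duplicated(key)
  src <- src[!dup]; tgt <- tgt[!dup]; key <- key[!dup]
  has <- function(a, b) ((a - 1) * n + b) %in% key

  out_nb <- split(tgt, factor(src, levels = seq_len(n)))
  in_nb <- split(src, factor(tgt, levels = seq_len(n)))
  din <- lengths(in_nb); dout <- lengths(out_nb)

  # FFL: x -> y, y -> z, x -> z
  ys <- which(din > 0 & dout > 0)
  X <- integer(0); Y <- integer(0); Z <- integer(0)
  if (length(ys)) {
    nx <- din[ys]; nz <- dout[ys]
    Y <- rep(ys, nx * nz)
    X <- unlist(lapply(ys, function(y) rep(in_nb[[y]], times = dout[y])),
                use.names = FALSE)
    Z <- unlist(lapply(ys, function(y) rep(out_nb[[y]], each = din[y])),
                use.names = FALSE)
    ok <- X != Z & has(X, Z)
    X <- X[ok]; Y <- Y[ok]; Z <- Z[ok]
    if (mode == "induced" && length(X)) {
      ok <- !has(Y, X) & !has(Z, Y) & !has(Z, X)
      X <- X[ok]; Y <- Y[ok]; Z <- Z[ok]
    }
  }

  # FBL: u -> v, v -> w, w -> u; canonical representative starts at the
  # smallest index, so each directed 3-cycle is counted once per node set.
  U <- integer(0); V <- integer(0); W <- integer(0)
  if (length(src)) {
    ws_list <- lapply(seq_along(src), function(e) {
      ws <- intersect(out_nb[[tgt[e]]], in_nb[[src[e]]])
      ws[ws != src[e] & ws != tgt[e]]
    })
    nw <- lengths(ws_list)
    U <- rep(src, nw); V <- rep(tgt, nw)
    W <- unlist(ws_list, use.names = FALSE)
    ok <- U < V & U < W
    U <- U[ok]; V <- V[ok]; W <- W[ok]
    if (mode == "induced" && length(U)) {
      ok <- !has(V, U) & !has(W, V) & !has(U, W)
      U <- U[ok]; V <- V[ok]; W <- W[ok]
    } else if (length(U)) {
      # both cycle orientations can match when reverse edges exist
      ok <- !duplicated(paste(U, pmin(V, W), pmax(V, W)))
      U <- U[ok]; V <- V[ok]; W <- W[ok]
    }
  }

  res <- list(n_ffl = length(X), n_fbl = length(U))
  if (want_instances) {
    res$ffl <- cbind(x = X, y = Y, z = Z)
    res$fbl <- cbind(a = U, b = V, c = W)
  }
  res
}

#' Census of 3-node motifs (feed-forward and feedback loops)
#'
#' Enumerates feed-forward loops (FFL: X regulates Y and Z, Y regulates Z)
#' and feedback loops (FBL: directed 3-cycle) over the simple digraph of
#' distinct directed adjacencies, self-loops excluded. In `induced` mode
#' (the default, the usual subgraph-census convention) a triple counts for a
#' class only if no extra edges exist among the three nodes; in `match` mode
#' every role assignment satisfying the edge pattern is counted. FFLs are
#' counted per role assignment, FBLs once per unordered node set.
#'
#' @param network A `regulatory_network`.
#' @param mode `"induced"` or `"match"`.
#' @return A `motif_census`: list with `counts` (tibble `motif`, `n`,
#'   `mode`), `ffl` (tibble `x`, `y`, `z`, `contains_mirna`,
#'   `mirna_position` one of `"X"`, `"Y"`, `"Z"`, `"multiple"` or `NA`),
#'   `fbl` (tibble `a`, `b`, `c`) and `nodes` (the node table used).
#' @export
census_triads <- function(network, mode = c("induced", "match")) {
  stopifnot(inherits(network, "regulatory_network"))
  mode <- match.arg(mode)
  ids <- network$nodes$id
  n <- length(ids)
  edges <- network$edges[!network$edges$self_loop, , drop = FALSE]
  res <- .count_motifs(n, match(edges$source, ids), match(edges$target, ids),
                       mode = mode, want_instances = TRUE)
  is_mir <- network$nodes$role == "mirna"
  ffl <- tibble::tibble(x = ids[res$ffl[, "x"]], y = ids[res$ffl[, "y"]],
                        z = ids[res$ffl[, "z"]])
  mx <- is_mir[res$ffl[, "x"]]; my <- is_mir[res$ffl[, "y"]]
  mz <- is_mir[res$ffl[, "z"]]
  npos <- mx + my + mz
  ffl$contains_mirna <- npos > 0
  ffl$mirna_position <- dplyr::case_when(
    npos > 1 ~ "multiple",
    mx ~ "X", my ~ "Y", mz ~ "Z",
    TRUE ~ NA_character_
  )
  fbl <- tibble::tibble(a = ids[res$fbl[, "a"]], b = ids[res$fbl[, "b"]],
                        c = ids[res$fbl[, "c"]])
  out <- list(
    counts = tibble::tibble(motif = c("FFL", "FBL"),
                            n = c(res$n_ffl, res$n_fbl), mode = mode),
    ffl = ffl, fbl = fbl, nodes = network$nodes, mode = mode
  )
  class(out) <- "motif_census"
  out
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("<motif_census mode=%s>\n", x$mode))
  print(x$counts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.motif_census <- function(x, ...) x$ffl

#' @exportS3Method generics::glance
glance.motif_census <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 n_ffl = x$counts$n[x$counts$motif == "FFL"],
                 n_fbl = x$counts$n[x$counts$motif == "FBL"],
                 n_mirna_ffl = sum(x$ffl$contains_mirna))
}

# Sample `m` distinct ordered non-self pairs uniformly among `n` nodes.
.sample_digraph <- function(n, m) {
  idx <- sample.int(n * (n - 1), m) - 1L
  s <- idx %/% (n - 1L) + 1L
  r <- idx %% (n - 1L) + 1L
  t <- ifelse(r < s, r, r + 1L)
  list(src = s, tgt = t)
}

#' Permutation-null Z-scores for motif enrichment
#'
#' Each permutation draws a simple digraph preserving the number of nodes
#' and the number of (distinct, non-self) directed edges while randomising
#' the connections (`size_only`, the literal null of the source analysis);
#' `role_preserving` additionally redraws each edge class only among
#' role-compatible node pairs, preserving per-class edge counts. The Z-score
#' is (observed - null mean) / null sd per motif class.
#'
#' @param network A `regulatory_network`.
#' @param n_perm Number of permutations (>= 2; 1000 in the original
#'   analysis).
#' @param seed Integer seed; results are bit-for-bit reproducible for a
#'   fixed seed and permutation count.
#' @param constraint `"size_only"` or `"role_preserving"`.
#' @param mode Census mode passed to the motif counter.
#' @return A tibble of class `motif_enrichment`: `motif`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `n_perm`, `seed`, `constraint`, `mode`.
#'   When the null sd is zero, Z is 0 if observed equals the mean and
#'   signed `Inf` (with a warning) otherwise.
#' @export
permutation_zscore <- function(network, n_perm = 1000, seed = 1,
                               constraint = c("size_only", "role_preserving"),
                               mode = c("induced", "match")) {
  stopifnot(inherits(network, "regulatory_network"), n_perm >= 2)
  constraint <- match.arg(constraint)
  mode <- match.arg(mode)
  ids <- network$nodes$id
  n <- length(ids)
  edges <- network$edges[!network$edges$self_loop, , drop = FALSE]
  src <- match(edges$source, ids); tgt <- match(edges$target, ids)
  obs <- .count_motifs(n, src, tgt, mode = mode)

  m_simple <- nrow(dplyr::distinct(tibble::tibble(src, tgt)))
  class_pairs <- NULL
  if (constraint == "role_preserving") {
    role <- network$nodes$role
    class_pairs <- lapply(split(seq_len(nrow(edges)), edges$edge_class),
                          length)
    src_pool <- lapply(EDGE_CLASSES, function(cl)
      which(role %in% .edge_source_roles[[cl]]))
    tgt_pool <- lapply(EDGE_CLASSES, function(cl)
      which(role %in% .edge_target_roles[[cl]]))
    names(src_pool) <- names(tgt_pool) <- EDGE_CLASSES
  }

  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      if (constraint == "size_only") {
        g <- .sample_digraph(n, m_simple)
      } else {
        parts <- lapply(names(class_pairs), function(cl) {
          ns <- length(src_pool[[cl]]); nt <- length(tgt_pool[[cl]])
          m_cl <- class_pairs[[cl]]
          # draw over the role-compatible pair grid, drop self pairs and
          # duplicates, and top up until the class edge count is met
          draw <- function(k) {
            idx <- sample.int(ns * nt, min(k, ns * nt)) - 1L
            s <- src_pool[[cl]][idx %/% nt + 1L]
            t <- tgt_pool[[cl]][idx %% nt + 1L]
            cbind(s, t)
          }
          got <- draw(m_cl * 2 + 10)
          got <- got[got[, 1] != got[, 2], , drop = FALSE]
          got <- got[!duplicated(got), , drop = FALSE]
          tries <- 0
          while (nrow(got) < m_cl && tries < 50) {
            got <- rbind(got, draw(m_cl * 2 + 10))
            got <- got[got[, 1] != got[, 2], , drop = FALSE]
            got <- got[!duplicated(got), , drop = FALSE]
            tries <- tries + 1
          }
          got[seq_len(min(m_cl, nrow(got))), , drop = FALSE]
        })
        all <- do.call(rbind, parts)
        g <- list(src = all[, 1], tgt = all[, 2])
      }
      cnt <- .count_motifs(n, g$src, g$tgt, mode = mode)
      c(cnt$n_ffl, cnt$n_fbl)
    }, numeric(2))
  })

  make_row <- function(motif, observed, nulls) {
    mu <- mean(nulls); sdv <- stats::sd(nulls)
    if (sdv > 0) {
      z <- (observed - mu) / sdv
    } else if (observed == mu) {
      z <- 0
    } else {
      warning("null sd is zero with observed != mean; Z reported as Inf")
      z <- sign(observed - mu) * Inf
    }
    tibble::tibble(motif = motif, observed = observed, null_mean = mu,
                   null_sd = sdv, z = z, n_perm = n_perm, seed = seed,
                   constraint = constraint, mode = mode)
  }
  out <- dplyr::bind_rows(make_row("FFL", obs$n_ffl, null_counts[1, ]),
                          make_row("FBL", obs$n_fbl, null_counts[2, ]))
  class(out) <- c("motif_enrichment", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.motif_enrichment <- function(x, ...) tibble::as_tibble(unclass(x))

#' Positions of miRNAs within feed-forward loops
#'
#' Tallies miRNA-containing FFLs by the position of the miRNA (input X,
#' intermediate Y, output Z). Proportions are taken over the
#' miRNA-containing FFLs; an FFL with miRNAs at several positions
#' contributes to each position (such loops are counted in attribute
#' `n_multi`), so position counts sum to at least the number of
#' miRNA-containing loops, with equality when each has exactly one miRNA.
#'
#' @param census A `motif_census`.
#' @param conserved_only Restrict to conserved miRNAs.
#' @return Tibble `position`, `n`, `proportion`; attributes
#'   `n_mirna_ffl` (denominator), `n_total_ffl`, `n_multi`.
#' @export
mirna_position_stats <- function(census, conserved_only = FALSE) {
  stopifnot(inherits(census, "motif_census"))
  flag <- census$nodes$role == "mirna"
  if (conserved_only) flag <- flag & census$nodes$conserved
  is_m <- stats::setNames(flag, census$nodes$id)
  ffl <- census$ffl
  mx <- unname(is_m[ffl$x]); my <- unname(is_m[ffl$y]); mz <- unname(is_m[ffl$z])
  denom <- sum(mx | my | mz)
  out <- tibble::tibble(
    position = c("X", "Y", "Z"),
    n = c(sum(mx), sum(my), sum(mz))
  )
  out$proportion <- if (denom > 0) out$n / denom else NA_real_
  attr(out, "n_mirna_ffl") <- denom
  attr(out, "n_total_ffl") <- nrow(ffl)
  attr(out, "n_multi") <- sum((mx + my + mz) > 1)
  out
}

#' Two-proportion chi-square test
#'
#' Pearson chi-square on the 2x2 table of successes/failures, without
#' continuity correction by default.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @param correct Apply the Yates continuity correction.
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(colSums(tab) == 0)) stop("zero margin in 2x2 table", call. = FALSE)
  ht <- stats::chisq.test(tab, correct = correct)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Classify the coherence of feed-forward loops from edge signs
#'
#' The indirect path sign is the product of the X->Y and Y->Z signs
#' (activating = +1, repressing = -1); the loop is coherent when it equals
#' the direct X->Z sign, incoherent otherwise, and unclassified whenever
#' any sign is unknown.
#'
#' @param sign_xy,sign_yz,sign_xz Character vectors among `activating`,
#'   `repressing`, `unknown` (`NA` treated as unknown).
#' @return Character vector: `coherent`, `incoherent` or `unclassified`.
#' @export
#' @examples
#' # a TF activating a miRNA that represses a target the TF also represses
#' classify_coherence("activating", "repressing", "repressing")  # coherent
classify_coherence <- function(sign_xy, sign_yz, sign_xz) {
  num <- function(s) dplyr::case_when(s == "activating" ~ 1,
                                      s == "repressing" ~ -1,
                                      TRUE ~ NA_real_)
  ind <- num(sign_xy) * num(sign_yz)
  dir <- num(sign_xz)
  dplyr::case_when(is.na(ind) | is.na(dir) ~ "unclassified",
                   ind == dir ~ "coherent",
                   TRUE ~ "incoherent")
}

#' Annotate census FFL instances with coherence labels
#'
#' Looks up edge signs in the source network (conflicting signs across edge
#' classes on the same node pair are treated as unknown) and adds a
#' `coherence` column to the FFL instance table.
#'
#' @param census A `motif_census`.
#' @param network The `regulatory_network` the census was computed on.
#' @return The `motif_census` with `ffl$coherence` added.
#' @export
annotate_coherence <- function(census, network) {
  stopifnot(inherits(census, "motif_census"),
            inherits(network, "regulatory_network"))
  e <- network$edges
  sg <- e %>%
    dplyr::group_by(.data$source, .data$target) %>%
    dplyr::summarise(
      sign = if (dplyr::n_distinct(.data$sign[.data$sign != "unknown"]) == 1)
        setdiff(unique(.data$sign), "unknown") else "unknown",
      .groups = "drop")
  key <- paste(sg$source, sg$target, sep = "\r")
  lookup <- stats::setNames(sg$sign, key)
  gs <- function(a, b) {
    s <- unname(lookup[paste(a, b, sep = "\r")])
    ifelse(is.na(s), "unknown", s)
  }
  ffl <- census$ffl
  census$ffl$coherence <- classify_coherence(
    gs(ffl$x, ffl$y), gs(ffl$y, ffl$z), gs(ffl$x, ffl$z))
  census
}
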