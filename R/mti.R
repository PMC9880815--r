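.pair_key <- function(df) paste(df$mirna_id, df$gene_id, sep = "\r")

.as_pair_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("mirna_id", "gene_id") %in% names(x)))
  dplyr::distinct(x[, c("mirna_id", "gene_id")])
}

#' Read a target-predictor output table, applying the penalty-score filter
#'
#' Predictor tables are TSV `mirna gene program score`; the filter retains
#' records with penalty score less than or equal to the threshold (the
#' standard for filtering is the penalty score of the miRNA-target
#' alignment; defaults used in practice are 2.2/2.5 for one program and
#' 2.5/3.0 for the other).
#'
#' @param path TSV path with columns `mirna`, `gene`, `score` (a `program`
#'   column is tolerated).
#' @param threshold Maximum penalty score retained.
#' @return Tibble `mirna_id`, `gene_id`, `score`.
#' @export
read_predictions <- function(path, threshold = 2.5) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  out <- tibble::tibble(mirna_id = as.character(df$mirna),
                        gene_id = as.character(df$gene),
                        score = as.numeric(df$score))
  dplyr::distinct(out[out$score <= threshold, , drop = FALSE],
                  .data$mirna_id, .data$gene_id, .keep_all = TRUE)
}

#' Merge miRNA-target predictions from two programs with degradome support
#'
#' A pair is retained if it is predicted by both programs, or by either
#' program while being compatible with (supported by) the degradome data:
#' result = (A intersect B) union ((A union B) intersect degradome-supported).
#'
#' @param pred_a,pred_b Data frames with columns `mirna_id`, `gene_id`
#'   (already thresholded per program).
#' @param degradome Data frame with columns `mirna_id`, `gene_id` and
#'   optionally `supported` (logical; missing column means all listed pairs
#'   are supported) and `category`.
#' @return Tibble `mirna_id`, `gene_id`, `provenance` with provenance one of
#'   `both_programs`, `degradome_supported` (single-program rescue) or
#'   `both` (in both programs and degradome-supported).
#' @export
#' @examples
#' a <- data.frame(mirna_id = c("m1", "m1", "m2"), gene_id = c("ga", "gb", "gc"))
#' b <- data.frame(mirna_id = c("m1", "m2", "m2"), gene_id = c("gb", "gc", "gd"))
#' d <- data.frame(mirna_id = c("m1", "m2", "m9"), gene_id = c("ga", "gd", "gz"))
#' merge_mti(a, b, d)   # ga via degradome, gb/gc via both programs, gd rescued
merge_mti <- function(pred_a, pred_b, degradome = NULL) {
  a <- .as_pair_tbl(pred_a); b <- .as_pair_tbl(pred_b)
  if (is.null(degradome) || nrow(tibble::as_tibble(degradome)) == 0) {
    supp <- tibble::tibble(mirna_id = character(), gene_id = character())
  } else {
    dg <- tibble::as_tibble(degradome)
    if ("supported" %in% names(dg)) dg <- dg[isTRUE_vec(dg$supported), , drop = FALSE]
    supp <- .as_pair_tbl(dg)
  }
  ka <- .pair_key(a); kb <- .pair_key(b); ks <- .pair_key(supp)
  uni <- dplyr::distinct(dplyr::bind_rows(a, b))
  ku <- .pair_key(uni)
  in_both <- ku %in% ka & ku %in% kb
  supported <- ku %in% ks
  keep <- in_both | supported
  out <- uni[keep, , drop = FALSE]
  out$provenance <- dplyr::case_when(
    in_both[keep] & supported[keep] ~ "both",
    in_both[keep] ~ "both_programs",
    TRUE ~ "degradome_supported"
  )
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Add curated/validated MTIs to the pipeline set
#'
#' Union of the pipeline pairs with a curated list; curated pairs absent
#' from the pipeline are tagged `curated`, so that the final count is
#' |pipeline| + |curated not in pipeline| (a pipeline of 2712 pairs plus 111
#' disjoint validated pairs yields the compiled set of 2823).
#'
#' @param pipeline_set Data frame with `mirna_id`, `gene_id` (a `provenance`
#'   column is preserved).
#' @param curated Data frame with `mirna_id`, `gene_id`.
#' @return Tibble `mirna_id`, `gene_id`, `provenance`.
#' @export
add_validated <- function(pipeline_set, curated) {
  p <- tibble::as_tibble(pipeline_set)
  if (!"provenance" %in% names(p)) p$provenance <- "pipeline"
  p <- dplyr::distinct(p[, c("mirna_id", "gene_id", "provenance")],
                       .data$mirna_id, .data$gene_id, .keep_all = TRUE)
  cu <- .as_pair_tbl(curated)
  new <- cu[!(.pair_key(cu) %in% .pair_key(p)), , drop = FALSE]
  if (nrow(new)) new$provenance <- "curated"
  dplyr::bind_rows(p, new)
}

#' Evaluate candidate MTI sets against a validated benchmark
#'
#' Recovery is the fraction of benchmark pairs present in the candidate set;
#' the report is sorted by recovery, then by set size, leaving the choice of
#' operating point (coverage vs false-positive tradeoff) to the user.
#'
#' @param candidate_sets Named list of data frames with `mirna_id`, `gene_id`.
#' @param benchmark Nonempty data frame with `mirna_id`, `gene_id`.
#' @return Tibble `set`, `size`, `n_recovered`, `recovery`.
#' @export
benchmark_eval <- function(candidate_sets, benchmark) {
  bm <- .as_pair_tbl(benchmark)
  if (nrow(bm) == 0) stop("empty benchmark", call. = FALSE)
  kb <- .pair_key(bm)
  rows <- purrr::imap(candidate_sets, function(cs, nm) {
    cs <- .as_pair_tbl(cs)
    tibble::tibble(set = nm, size = nrow(cs),
                   n_recovered = sum(kb %in% .pair_key(cs)))
  })
  out <- dplyr::bind_rows(rows)
  out$recovery <- out$n_recovered / nrow(bm)
  dplyr::arrange(out, dplyr::desc(.data$recovery), dplyr::desc(.data$size))
}

#' Locate a miRNA binding site within the transcript model
#'
#' Maps a binding-site start coordinate (0-based position on the mature
#' transcript) to its containing segment (5' UTR, CDS or 3' UTR) and a
#' position normalised to `[0, 1]` within that segment (0 = first base,
#' 1 = last base; 0 for single-base segments).
#'
#' @param utr5_len,cds_len,utr3_len Segment lengths in nt (any may be 0).
#' @param mbs_start Binding-site start position(s), 0-based, within the
#'   transcript.
#' @return Tibble `mbs_start`, `region`, `position`.
#' @export
mbs_relative_position <- function(utr5_len, cds_len, utr3_len, mbs_start) {
  total <- utr5_len + cds_len + utr3_len
  if (any(mbs_start < 0 | mbs_start >= total)) {
    stop("mbs_start beyond transcript bounds", call. = FALSE)
  }
  starts <- c(five_prime_utr = 0, cds = utr5_len, three_prime_utr = utr5_len + cds_len)
  lens <- c(five_prime_utr = utr5_len, cds = cds_len, three_prime_utr = utr3_len)
  region <- ifelse(mbs_start < utr5_len, "five_prime_utr",
                   ifelse(mbs_start < utr5_len + cds_len, "cds", "three_prime_utr"))
  pos <- (mbs_start - starts[region]) / pmax(lens[region] - 1, 1)
  tibble::tibble(mbs_start = mbs_start, region = unname(region),
                 position = unname(pos))
}
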