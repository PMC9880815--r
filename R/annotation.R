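#' Binding-window parameters
#'
#' Strand-aware windows used to link a ChIP binding peak to a locus: for
#' protein-coding genes the window runs from 2000 bp upstream to 300 bp
#' downstream of the TSS; for miRNA loci from 2000 bp upstream of the first
#' base of the pre-miRNA (no downstream extension).
#'
#' @param coding_upstream,coding_downstream,mirna_upstream,mirna_downstream
#'   Nonnegative window extents in bp.
#' @return A list of class `window_params`.
#' @export
window_params <- function(coding_upstream = 2000, coding_downstream = 300,
                          mirna_upstream = 2000, mirna_downstream = 0) {
  p <- list(coding_upstream = coding_upstream,
            coding_downstream = coding_downstream,
            mirna_upstream = mirna_upstream,
            mirna_downstream = mirna_downstream)
  if (any(unlist(p) < 0)) stop("window extents must be nonnegative", call. = FALSE)
  structure(p, class = "window_params")
}

#' Compute strand-aware binding windows around gene anchors
#'
#' Coordinates are 0-based; the anchor is the position of the first
#' transcribed base (TSS for coding genes, first base of the pre-miRNA for
#' miRNA loci). On the plus strand the window is `[anchor - upstream,
#' anchor + downstream]`; on the minus strand `[anchor - downstream,
#' anchor + upstream]`. Windows are closed (inclusive at both ends) and
#' clipped at 0.
#'
#' @param anchors Data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `anchor`, `gene_class` (`"coding"` or `"mirna"`).
#' @param params A [window_params()] object.
#' @return The anchor tibble with `win_start` and `win_end` columns added.
#' @export
#' @examples
#' a <- data.frame(gene_id = "g", chrom = "Chr1", strand = "+",
#'                 anchor = 10000, gene_class = "coding")
#' compute_window(a, window_params())[, c("win_start", "win_end")]
compute_window <- function(anchors, params = window_params()) {
  stopifnot(inherits(params, "window_params"))
  anchors <- tibble::as_tibble(anchors)
  stopifnot(all(c("gene_id", "chrom", "strand", "anchor", "gene_class") %in%
                  names(anchors)))
  if (!all(anchors$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  up <- ifelse(anchors$gene_class == "mirna", params$mirna_upstream,
               params$coding_upstream)
  down <- ifelse(anchors$gene_class == "mirna", params$mirna_downstream,
                 params$coding_downstream)
  plus <- anchors$strand == "+"
  anchors$win_start <- pmax(0L, ifelse(plus, anchors$anchor - up,
                                       anchors$anchor - down))
  anchors$win_end <- ifelse(plus, anchors$anchor + down, anchors$anchor + up)
  anchors
}

.peak_midpoint <- function(start, end) floor((start + end) / 2)

#' Assign binding peaks to genes by the midpoint rule
#'
#' A peak is assigned to a gene if the midpoint of the peak (the lower median
#' base for even-length peaks, 0-based half-open input coordinates) falls
#' within the gene's strand-aware binding window. A peak may be assigned to
#' several genes when windows overlap; use [peak_edge_table()] to collapse
#' assignments to unique candidate (TF, gene) edges.
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `tf_id` and optionally `score`.
#' @param anchors Anchor table as for [compute_window()].
#' @param params A [window_params()] object.
#' @return Tibble with one row per (peak, gene) assignment: `peak_id`
#'   (input row number), `tf_id`, `gene_id`, `gene_class`, `midpoint` and
#'   the strand-oriented `offset` of the midpoint from the anchor (negative
#'   = upstream). Peaks on chromosomes absent from the anchor table are
#'   counted in attribute `n_chrom_unmatched`.
#' @export
assign_peaks_to_genes <- function(peaks, anchors, params = window_params()) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("chrom", "start", "end", "tf_id") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) stop("peak start must be < end", call. = FALSE)
  win <- compute_window(anchors, params)
  mid <- .peak_midpoint(peaks$start, peaks$end)
  empty <- tibble::tibble(peak_id = integer(), tf_id = character(),
                          gene_id = character(), gene_class = character(),
                          midpoint = numeric(), offset = numeric())
  if (nrow(peaks) == 0 || nrow(win) == 0) {
    attr(empty, "n_chrom_unmatched") <- nrow(peaks)
    return(empty)
  }
  # 1-based closed ranges for the overlap engine
  pk <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1, mid + 1))
  wn <- GenomicRanges::GRanges(win$chrom,
                               IRanges::IRanges(win$win_start + 1, win$win_end + 1))
  hits <- GenomicRanges::findOverlaps(pk, wn, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  out <- tibble::tibble(
    peak_id = i,
    tf_id = peaks$tf_id[i],
    gene_id = win$gene_id[j],
    gene_class = win$gene_class[j],
    midpoint = mid[i],
    offset = ifelse(win$strand[j] == "+", mid[i] - win$anchor[j],
                    win$anchor[j] - mid[i])
  )
  attr(out, "n_chrom_unmatched") <- sum(!peaks$chrom %in% unique(win$chrom))
  out
}

#' Collapse peak assignments to candidate regulatory edges
#'
#' Unique (TF, gene) pairs from a peak assignment table, with supporting
#' peak counts; TMI edges for miRNA loci, TTI edges for coding genes. The
#' result feeds [assemble_network()] directly.
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @return Tibble `source`, `target`, `edge_class`, `n_peaks`.
#' @export
peak_edge_table <- function(assignments) {
  out <- assignments %>%
    dplyr::count(.data$tf_id, .data$gene_id, .data$gene_class, name = "n_peaks")
  tibble::tibble(source = out$tf_id, target = out$gene_id,
                 edge_class = ifelse(out$gene_class == "mirna", "TMI", "TTI"),
                 n_peaks = out$n_peaks)
}

#' Classify the genomic context of peak midpoints
#'
#' Labels each peak by the annotated feature containing its midpoint, with a
#' configurable priority when features overlap (default: 5' UTR, then 3' UTR,
#' then exon, then intron, then intergenic). A midpoint inside a gene body
#' but outside any exon/UTR feature is intronic; outside all gene bodies it
#' is intergenic.
#'
#' @param peaks Peak table as in [assign_peaks_to_genes()].
#' @param features Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `type` among `gene`, `exon`, `five_prime_utr`,
#'   `three_prime_utr`.
#' @param priority Character vector ordering the non-intergenic labels.
#' @return The peak tibble with `midpoint` and `context` columns added.
#' @export
classify_peak_context <- function(peaks, features,
                                  priority = c("five_prime_utr",
                                               "three_prime_utr",
                                               "exon", "intron")) {
  peaks <- tibble::as_tibble(peaks)
  features <- tibble::as_tibble(features)
  mid <- .peak_midpoint(peaks$start, peaks$end)
  lab <- rep("intergenic", nrow(peaks))
  in_type <- function(type, m, chrom) {
    f <- features[features$type == type, , drop = FALSE]
    if (nrow(f) == 0) return(rep(FALSE, length(m)))
    vapply(seq_along(m), function(k) {
      any(f$chrom == chrom[k] & f$start <= m[k] & m[k] < f$end)
    }, logical(1))
  }
  hit <- list(
    five_prime_utr = in_type("five_prime_utr", mid, peaks$chrom),
    three_prime_utr = in_type("three_prime_utr", mid, peaks$chrom),
    exon = in_type("exon", mid, peaks$chrom),
    gene = in_type("gene", mid, peaks$chrom)
  )
  hit$intron <- hit$gene & !(hit$exon | hit$five_prime_utr | hit$three_prime_utr)
  for (type in rev(priority)) lab[hit[[type]]] <- type
  peaks$midpoint <- mid
  peaks$context <- lab
  peaks
}

#' Metagene profile of peak midpoints around anchors
#'
#' Bins strand-oriented offsets of peak midpoints relative to every anchor
#' (negative = upstream of the first transcribed base). The histogram counts
#' each (peak, anchor) combination whose offset lies in `[window[1],
#' window[2])`, so it sums to the number of in-window midpoint placements.
#'
#' @param peaks Peak table.
#' @param anchors Anchor table (see [compute_window()]).
#' @param window Length-2 numeric, offset range in bp.
#' @param bin Bin width in bp; must divide the window length.
#' @return Tibble `bin_start`, `bin_mid`, `n`.
#' @export
metagene_profile <- function(peaks, anchors, window = c(-2000, 300), bin = 50) {
  if (nrow(tibble::as_tibble(anchors)) == 0) stop("no anchors", call. = FALSE)
  span <- window[2] - window[1]
  if (span <= 0 || span %% bin != 0) {
    stop("`bin` must divide the window length", call. = FALSE)
  }
  peaks <- tibble::as_tibble(peaks)
  anchors <- tibble::as_tibble(anchors)
  mid <- .peak_midpoint(peaks$start, peaks$end)
  offs <- unlist(lapply(seq_len(nrow(anchors)), function(j) {
    same <- which(peaks$chrom == anchors$chrom[j])
    if (anchors$strand[j] == "+") mid[same] - anchors$anchor[j]
    else anchors$anchor[j] - mid[same]
  }))
  breaks <- seq(window[1], window[2], by = bin)
  offs <- offs[offs >= window[1] & offs < window[2]]
  cnt <- table(cut(offs, breaks = breaks, right = FALSE))
  tibble::tibble(bin_start = breaks[-length(breaks)],
                 bin_mid = breaks[-length(breaks)] + bin / 2,
                 n = as.integer(cnt))
}

# ---- BED / GFF3 interchange ------------------------------------------------

#' Read peaks from BED and anchors/structures from GFF3
#'
#' BED input (0-based half-open) maps the name column to `tf_id`. GFF3 input
#' (1-based inclusive, converted on read) yields anchors from `gene` and
#' `miRNA_primary_transcript` features (anchor = first transcribed base,
#' strand-aware) and a structure table from `gene`, `exon`,
#' `five_prime_UTR` and `three_prime_UTR` features.
#'
#' @param path File path.
#' @return `read_peaks_bed()`: a peak tibble. `read_anchors_gff3()`: a list
#'   with `anchors` and `features` tibbles.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    tf_id = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  )
}

#' @rdname read_peaks_bed
#' @export
read_anchors_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) gr$ID else NA_character_
  )
  is_anchor <- df$type %in% c("gene", "miRNA_primary_transcript")
  an <- df[is_anchor, , drop = FALSE]
  anchors <- tibble::tibble(
    gene_id = an$id,
    chrom = an$chrom,
    strand = an$strand,
    anchor = ifelse(an$strand == "+", an$start, an$end - 1L),
    gene_class = ifelse(an$type == "miRNA_primary_transcript", "mirna", "coding")
  )
  fmap <- c(gene = "gene", exon = "exon", five_prime_UTR = "five_prime_utr",
            three_prime_UTR = "three_prime_utr")
  fe <- df[df$type %in% names(fmap), , drop = FALSE]
  features <- tibble::tibble(chrom = fe$chrom, start = fe$start, end = fe$end,
                             type = unname(fmap[fe$type]))
  list(anchors = anchors, features = features)
}

#' Write peaks to BED6 and anchors to GFF3
#'
#' @param peaks,anchors Tables as used elsewhere in the package (`anchors`
#'   may carry an optional `length` column giving the locus length in bp,
#'   default 1000 for coding genes and 200 for miRNA loci).
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname read_peaks_bed
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  gr$name <- peaks$tf_id
  gr$score <- if ("score" %in% names(peaks)) peaks$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname read_peaks_bed
#' @export
write_anchors_gff3 <- function(anchors, path) {
  anchors <- tibble::as_tibble(anchors)
  len <- if ("length" %in% names(anchors)) anchors$length else
    ifelse(anchors$gene_class == "mirna", 200L, 1000L)
  plus <- anchors$strand == "+"
  start0 <- ifelse(plus, anchors$anchor, anchors$anchor - len + 1L)
  gr <- GenomicRanges::GRanges(
    anchors$chrom,
    IRanges::IRanges(start0 + 1L, start0 + len),
    strand = anchors$strand)
  gr$type <- ifelse(anchors$gene_class == "mirna",
                    "miRNA_primary_transcript", "gene")
  gr$ID <- anchors$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
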