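#' Degree distribution plot on log-log axes
#'
#' @param network A `regulatory_network`.
#' @param which `"total"`, `"in"` or `"out"` degree.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(network, which = c("total", "in", "out")) {
  which <- match.arg(which)
  prof <- degree_profile(network)
  deg <- switch(which, total = prof$degree, `in` = prof$d_in, out = prof$d_out)
  df <- dplyr::count(tibble::tibble(degree = deg[deg > 0]), .data$degree)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste(which, "degree"), y = "number of nodes") +
    ggplot2::theme_minimal()
}

#' Average O/T ratio by node role
#'
#' Bar chart of the mean out-degree over total-degree ratio per role, with
#' the theoretical network-level value of 0.5 as a dashed line.
#'
#' @param network A `regulatory_network`.
#' @return A ggplot object.
#' @export
plot_ot_ratio <- function(network) {
  prof <- degree_profile(network)
  df <- prof %>%
    dplyr::filter(!is.na(.data$ot_ratio)) %>%
    dplyr::group_by(.data$role) %>%
    dplyr::summarise(mean_ot = mean(.data$ot_ratio), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$role, y = .data$mean_ot)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "average O/T ratio") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.motif_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$motif, y = .data$z)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Z score (permutation null)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.layer_assignment <- function(object, ...) {
  df <- layer_share(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "nodes") +
    ggplot2::theme_minimal()
}

#' Metagene profile plot of peak density around anchors
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin_mid, y = .data$n)) +
    ggplot2::geom_col(width = diff(profile$bin_start[1:2]) * 0.9,
                      fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "offset from anchor (bp; negative = upstream)",
                  y = "peak midpoints") +
    ggplot2::theme_minimal()
}

#' Position of miRNAs within FFLs
#'
#' @param stats Output of [mirna_position_stats()].
#' @return A ggplot object.
#' @export
plot_mirna_positions <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$position, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "miRNA position in FFL",
                  y = "proportion of miRNA-containing FFLs") +
    ggplot2::theme_minimal()
}
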