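#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-context methylation variability
#'
#' Boxplots of per-probe beta SD stratified by genomic context, the standard
#' view for deciding which CpG contexts carry cohort-level information.
#'
#' @param var_tbl Output of [variance_by_context()].
#' @param x,fill Context columns to map to the x axis and fill.
#' @return A ggplot object.
#' @export
plot_variance_by_context <- function(var_tbl, x = "genic_context",
                                     fill = "atac_overlap") {
  ggplot2::ggplot(var_tbl,
                  ggplot2::aes(x = .data[[x]], y = .data$sd,
                               fill = factor(.data[[fill]]))) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "beta SD", fill = fill) +
    ggplot2::theme_minimal()
}

#' Mixture-coefficient heat view of an epitype fit
#'
#' Samples ordered by cluster with their NMF mixture coefficients, the
#' compact diagnostic for how cleanly samples load on one factor.
#'
#' @param object An `epitype_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epitype_fit
#' @export
autoplot.epitype_fit <- function(object, ...) {
  td <- tidy(object) %>%
    dplyr::arrange(.data$cluster) %>%
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = .data$sample_id)) %>%
    tidyr::pivot_longer(dplyr::starts_with("h_"), names_to = "factor",
                        values_to = "coefficient")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$sample_id, y = .data$factor,
                                   fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "samples (ordered by cluster)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Volcano-style view of differential methylation results
#'
#' Effect size (max pairwise group mean difference, signed by direction when
#' two groups) against -log10 adjusted p.
#'
#' @param object Output of [diff_meth()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diff_meth_tbl
#' @export
autoplot.diff_meth_tbl <- function(object, ...) {
  d <- dplyr::filter(object, !.data$skipped, !is.na(.data$p_adj))
  mean_cols <- grep("^mean_", names(d), value = TRUE)
  eff <- if (length(mean_cols) == 2L) {
    d[[mean_cols[2L]]] - d[[mean_cols[1L]]]
  } else {
    d$delta
  }
  d$effect <- eff
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect,
                                  y = -log10(pmax(.data$p_adj, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "delta mean beta", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' CpG-gene correlation versus TSS distance
#'
#' @param pairs Pair table with `tss_distance`, `jackknife_r` and (after
#'   [call_significant_pairs()]) a `significant` flag.
#' @param cutoffs Optional `null_cutoffs` to draw as horizontal lines.
#' @return A ggplot object.
#' @export
plot_pair_correlations <- function(pairs, cutoffs = NULL) {
  d <- dplyr::filter(pairs, !is.na(.data$jackknife_r))
  base_aes <- ggplot2::aes(x = .data$tss_distance / 1000, y = .data$jackknife_r)
  p <- ggplot2::ggplot(d, base_aes)
  p <- if ("significant" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                            alpha = 0.4, size = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.4, size = 0.8)
  }
  p <- p +
    ggplot2::labs(x = "distance to TSS (kb)", y = "jackknife r",
                  colour = "significant") +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs)) {
    p <- p + ggplot2::geom_hline(yintercept = c(cutoffs$low, cutoffs$high),
                                 linetype = "dashed")
  }
  p
}
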