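#' Copy number by lineage, per paralog
#'
#' Boxplots of estimated copy number per paralog, split by lineage —
#' the visual companion of [cn_lineage_stats()].
#'
#' @param cn_table A `cn_table`.
#' @param drop_unassigned Exclude unassigned samples (default TRUE, matching
#'   the lineage ANOVAs).
#' @return A ggplot.
#' @export
plot_cn_lineage <- function(cn_table, drop_unassigned = TRUE) {
  long <- cn_long(cn_table)
  if (drop_unassigned) long <- dplyr::filter(long, .data$lineage != "unassigned")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lineage, y = .data$cn,
                                     fill = .data$lineage)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$paralog), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Estimated copy number") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Corrected vs uncorrected association p-values
#'
#' Scatter of per-paralog PGLS p-values against naive Pearson p-values
#' (log10 scale), making phylogenetic confounding visible: points far below
#' the diagonal are associations explained by relatedness.
#'
#' @param assoc An association tibble from [correlate_cn_chemotype()].
#' @return A ggplot.
#' @export
plot_association_pvalues <- function(assoc) {
  ggplot2::ggplot(assoc, ggplot2::aes(x = -log10(.data$p_pearson),
                                      y = -log10(.data$p_pgls),
                                      colour = .data$cannabinoid)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 p (uncorrected Pearson)",
                  y = "-log10 p (PGLS, corrected)") +
    ggplot2::theme_minimal()
}
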