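# ggplot2 helpers for the result tables.

#' ROC curve plot
#'
#' @param x A `tcr_eval` from [confusion_stats()] or the list returned by
#'   [roc_auc()].
#' @return A ggplot object.
#' @export
plot_roc <- function(x) {
  pts <- x$roc_points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path(colour = "#2166AC", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", x$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tcr_eval <- function(object, ...) plot_roc(object)

#' V-J usage preference heatmap
#'
#' @param pref Output of [vj_preference()].
#' @return A ggplot object (V genes x J genes, fill = log2 ratio).
#' @export
plot_vj_preference <- function(pref) {
  df <- tidyr::separate(pref, "vj", into = c("v_gene", "j_gene"), sep = "\\|")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j_gene, y = .data$v_gene,
                                   fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::labs(x = "J gene", y = "V gene", fill = "log2 ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Positional amino-acid preference heatmap
#'
#' @param pref Output of [positional_aa_preference()].
#' @return A ggplot object (position x amino acid, fill = log2 ratio).
#' @export
plot_positional_preference <- function(pref) {
  ggplot2::ggplot(pref, ggplot2::aes(x = .data$position, y = .data$aa,
                                     fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::labs(x = "CDR3 position", y = "Amino acid", fill = "log2 ratio") +
    ggplot2::theme_minimal()
}

#' Motif overlap curve plot
#'
#' @param curve Output of [motif_overlap_curve()].
#' @return A ggplot object.
#' @export
plot_motif_overlap <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n, y = .data$overlap_ratio)) +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::geom_point(colour = "#2166AC") +
    ggplot2::scale_x_log10() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Top n motifs", y = "Overlap ratio") +
    ggplot2::theme_minimal()
}

#' Diversity metric comparison plot
#'
#' @param div Output of [diversity_table()].
#' @param metric Column to plot (default `"shannon"`).
#' @return A ggplot box/jitter plot by group label.
#' @export
plot_diversity <- function(div, metric = "shannon") {
  ggplot2::ggplot(div, ggplot2::aes(x = .data$label, y = .data[[metric]],
                                    fill = .data$label)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
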