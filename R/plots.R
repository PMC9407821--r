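#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_rect labs scale_fill_gradient theme_minimal annotate
#' @export
ggplot2::autoplot

#' @describeIn pca_samples PC1/PC2 scatter, coloured by species when the
#'   sample sheet was joined.
#' @param object,... autoplot-interface arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.expr_pca <- function(object, ...) {
  scores <- object$scores
  pct <- function(i) sprintf("%s (%.1f%%)", object$explained$component[i],
                             100 * object$explained$fraction[i])
  p <- ggplot(scores, aes(x = .data$PC1, y = .data$PC2))
  p <- if ("species" %in% names(scores)) {
    p + geom_point(aes(colour = .data$species), size = 2.5)
  } else {
    p + geom_point(size = 2.5)
  }
  p + labs(x = pct(1), y = pct(2)) + theme_minimal()
}

#' @describeIn spearman_cluster Spearman correlation heat map of samples,
#'   ordered by the dendrogram.
#' @param object,... autoplot-interface arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.expr_clust <- function(object, ...) {
  ord <- object$tree$labels[object$tree$order]
  long <- object$correlation |>
    tidyr::pivot_longer(-"sample_id", names_to = "other", values_to = "rho") |>
    mutate(sample_id = factor(.data$sample_id, levels = ord),
           other = factor(.data$other, levels = ord))
  ggplot(long, aes(x = .data$sample_id, y = .data$other, fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "steelblue4", limits = c(NA, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman rho") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn metagene_profile methylation level along the 60-bin metagene
#'   axis, with the gene body shaded.
#' @param object,... autoplot-interface arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.metagene_profile <- function(object, ...) {
  n_bins <- nrow(object) / 3
  ggplot(object, aes(x = .data$bin, y = .data$level)) +
    annotate("rect", xmin = n_bins + 0.5, xmax = 2 * n_bins + 0.5,
             ymin = -Inf, ymax = Inf, alpha = 0.12) +
    geom_line(linewidth = 0.8) +
    ggplot2::scale_x_continuous(
      breaks = c(1, n_bins + 0.5, 2 * n_bins + 0.5, 3 * n_bins),
      labels = c("-2 kb", "TSS", "TES", "+2 kb")
    ) +
    labs(x = NULL, y = "CpG methylation level") +
    theme_minimal()
}

#' Metagene profile line plot
#'
#' Convenience wrapper around the `autoplot` method for metagene profiles.
#'
#' @param profile tibble from [metagene_profile()].
#' @return a ggplot object.
#' @export
plot_metagene <- function(profile) {
  autoplot.metagene_profile(profile)
}
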