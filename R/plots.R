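#' Violin plot of per-gene CV distributions by group
#'
#' The standard side-by-side view of expression diversity in the two groups,
#' optionally restricted to a gene subset (e.g. the CSGS).
#'
#' @param cvs A [cv_table()].
#' @param genes Optional gene-id subset.
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_cv_distribution <- function(cvs, genes = NULL, title = NULL) {
  if (!is.null(genes)) cvs <- filter(cvs, .data$gene_id %in% genes)
  ggplot2::ggplot(cvs, ggplot2::aes(x = .data$group, y = .data$cv,
                                    fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 23, size = 3,
                          fill = "white") +
    ggplot2::labs(x = NULL, y = "Per-gene CV of expression",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Genome-wide window-score scan plot
#'
#' Window scores along the genome, faceted by chromosome, with the
#' top-quantile threshold and called sweep regions highlighted when given.
#'
#' @param windows Scored window tibble (`chrom`, `start`, `end`, `score`).
#' @param regions Optional `sweep_regions` tibble to shade.
#' @param threshold Optional horizontal threshold line.
#' @return A ggplot.
#' @export
plot_window_scores <- function(windows, regions = NULL, threshold = NULL) {
  p <- ggplot2::ggplot(filter(windows, !is.na(.data$score)),
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$score)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Window score") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(regions),
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.15,
      inherit.aes = FALSE)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' Bar chart of a diversity report
#'
#' D_cv per gene set with significance stars, the summary view of a
#' domestic-vs-wild comparison across WGGS/CSGS/non-CSGS.
#'
#' @param report Output of [report_diversity_table()].
#' @return A ggplot.
#' @export
plot_diversity_report <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$gene_set,
                                       y = .data$d_cv_percent)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "Decrease of expression diversity (%)") +
    ggplot2::theme_minimal()
}
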