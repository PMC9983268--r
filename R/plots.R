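#' Violin plots of the six fidelity metrics
#'
#' One panel per metric (gene-wise mean, variance, cv, zero proportion;
#' location-wise zero proportion and library size), reference next to
#' synthetic. Heavy-tailed metrics (mean, variance, cv, library size) are
#' shown on a log10 scale with zeros dropped from those panels only.
#'
#' @param report An `srt_fidelity` from [fidelity_report()].
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(report) {
  gm <- tidyr::pivot_longer(report$gene_metrics,
                            c("mean", "variance", "cv", "zero_prop"),
                            names_to = "metric")
  gm$metric <- paste0("gene ", gm$metric)
  lm_ <- tidyr::pivot_longer(report$location_metrics,
                             c("zero_prop", "library_size"),
                             names_to = "metric")
  lm_$metric <- paste0("location ", lm_$metric)
  long <- dplyr::bind_rows(gm[, c("source", "metric", "value")],
                           lm_[, c("source", "metric", "value")])
  logged <- c("gene mean", "gene variance", "gene cv", "location library_size")
  long <- dplyr::filter(long, !is.na(.data$value),
                        !(.data$metric %in% logged & .data$value <= 0))
  long <- dplyr::mutate(long, value = ifelse(.data$metric %in% logged,
                                             log10(.data$value), .data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$source, y = .data$value,
                                     fill = .data$source)) +
    ggplot2::geom_violin(scale = "width", linewidth = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value (log10 where heavy-tailed)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Scatter plot of per-gene Moran's I, reference vs synthetic
#'
#' @param report An `srt_fidelity` computed on identical locations.
#' @return A ggplot object.
#' @export
plot_morans_concordance <- function(report) {
  if (is.null(report$morans)) {
    abort("Moran's I comparison requires identical locations in both datasets")
  }
  ggplot2::ggplot(report$morans,
                  ggplot2::aes(x = .data$reference, y = .data$synthetic)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "Moran's I (reference)", y = "Moran's I (synthetic)") +
    ggplot2::theme_minimal()
}

#' @method autoplot srt_fidelity
#' @export
autoplot.srt_fidelity <- function(object, ...) {
  p <- plot_metric_distributions(object)
  if (!is.null(object$morans) && requireNamespace("patchwork", quietly = TRUE)) {
    return(p + plot_morans_concordance(object) +
             patchwork::plot_layout(widths = c(2, 1)))
  }
  p
}

#' Spatial expression map of one gene
#'
#' @param data An [srt_data].
#' @param gene A gene identifier.
#' @param trans Count transform for colour (default `log1p`).
#' @return A ggplot object.
#' @export
plot_gene_spatial <- function(data, gene, trans = log1p) {
  stopifnot(gene %in% gene_ids(data))
  df <- dplyr::mutate(data$coords, value = trans(data$counts[gene, ]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = gene) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @method autoplot srt_data
#' @export
autoplot.srt_data <- function(object, ...) {
  df <- object$coords
  df$domain <- object$domains %||% "tissue"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$domain)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "domain") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
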