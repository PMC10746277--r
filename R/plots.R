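#' Volcano plot of gene-level fitness calls
#'
#' Median LFC against -log10 Stouffer p for one condition, with the
#' essentiality (-3) and fitness-defect (-1) LFC cutoffs and the
#' significance cutoff drawn as dashed lines.
#'
#' @param gene_calls Tibble from [call_genes()].
#' @param condition Condition to plot (default "aerobic").
#' @param alpha Significance cutoff line (default 0.05).
#' @return A ggplot.
#' @export
plot_volcano <- function(gene_calls, condition = "aerobic", alpha = 0.05) {
  lfc_col <- paste0("median_lfc_", condition)
  p_col <- paste0("p_", condition)
  check_cols(gene_calls, c(lfc_col, p_col, "class_label"), "gene calls")
  df <- tibble(
    lfc = gene_calls[[lfc_col]],
    mlp = -log10(pmax(gene_calls[[p_col]], 1e-300)),
    class_label = gene_calls$class_label
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc, y = .data$mlp,
                                   colour = .data$class_label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-3, -1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = sprintf("median LFC (%s)", condition),
                  y = "-log10 combined p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of gene classification counts
#'
#' @param gene_calls Tibble from [call_genes()].
#' @return A ggplot.
#' @export
plot_gene_classes <- function(gene_calls) {
  check_cols(gene_calls, "class_label", "gene calls")
  df <- count(gene_calls, .data$class_label, name = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$class_label, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Fitted dispersion trend
#'
#' @param trend A `dispersion_trend`.
#' @return A ggplot of phi against the normalized mean.
#' @export
plot_dispersion_trend <- function(trend) {
  stopifnot(inherits(trend, "dispersion_trend"))
  df <- tibble(mu = trend$mu, phi = trend$phi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mu, y = .data$phi)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "normalized mean", y = "dispersion phi") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano autoplot for a screen result
#'
#' @param object A `crispri_screen`.
#' @param condition Condition to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crispri_screen <- function(object, condition = NULL, ...) {
  condition <- condition %||% object$params$conditions[1]
  plot_volcano(object$gene_calls, condition, alpha = object$params$alpha)
}
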