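# ggplot2 presentation layer. Numeric tables are the contract; these are
# convenience views in the layouts the field uses.

#' Plot an ENC-plot (ENC vs GC3s with the expected curve)
#'
#' @param object an `enc_table` from [enc_table()].
#' @param ... unused.
#' @return A ggplot: one point per gene, the mutation-only expected curve
#'   sampled densely on `[0, 1]`.
#' @export
autoplot.enc_table <- function(object, ...) {
  curve <- tibble(gc3s = seq(0, 1, by = 0.005))
  curve$enc <- enc_expected(curve$gc3s)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gc3s, y = .data$enc_obs)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$enc),
                       linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), size = 2.6,
                       vjust = -0.8, check_overlap = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 64)) +
    ggplot2::labs(x = "GC3s", y = "ENC",
                  title = "ENC-plot",
                  subtitle = "curve: expected ENC under mutation pressure alone") +
    ggplot2::theme_minimal()
}

#' Plot a neutrality fit (GC12 vs GC3 with the regression line)
#'
#' @param object a [neutrality_fit()].
#' @param ... unused.
#' @return A ggplot with the per-gene points, the fitted line and the
#'   diagonal GC12 = GC3 for reference.
#' @export
autoplot.neutrality_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$gc3, y = .data$gc12)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#b2182b") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(
      x = "GC3", y = "GC12", title = "Neutrality plot",
      subtitle = sprintf("slope = %.3f, r = %.3f (p = %.3g), n = %d",
                         object$slope, object$r, object$p_value, object$n)) +
    ggplot2::theme_minimal()
}

#' RSCU bar chart
#'
#' Stacked per-amino-acid RSCU bars (codons shown in the RNA alphabet), the
#' standard comparative codon-usage figure; faceted by species when the
#' input has a `species` column (e.g. `rscu_long` from [mito_compare()]).
#'
#' @param rscu_tbl output of [rscu()], optionally with a `species` column.
#' @return A ggplot.
#' @export
plot_rscu <- function(rscu_tbl) {
  p <- ggplot2::ggplot(rscu_tbl,
                       ggplot2::aes(x = .data$aa, y = .data$rscu,
                                    fill = .data$codon_rna)) +
    ggplot2::geom_col(colour = "white", linewidth = 0.1) +
    ggplot2::labs(x = "amino acid", y = "RSCU", fill = "codon") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if ("species" %in% names(rscu_tbl)) {
    p <- p + ggplot2::facet_wrap(~species)
  }
  p
}
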