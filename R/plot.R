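#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot effect sizes of a breakage result set
#'
#' Horizontal bar chart of the allele-difference effect size for every
#' reported variant x motif pair, colored by effect class. Positive bars are
#' motifs weakened (disrupted) by the alternate allele, negative bars motifs
#' created or strengthened.
#'
#' @param object A `motif_breakage` tibble from [analyze_variants()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motif_breakage
#' @export
autoplot.motif_breakage <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pair <- paste(df$var_id, df$motif_id, sep = " | ")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$pair, .data$effect_size),
    y = .data$effect_size, fill = .data$effect_class
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(strong = "grey20", weak = "grey70")) +
    ggplot2::labs(
      x = NULL, y = "effect size (ref - alt normalized score)",
      fill = "effect class",
      title = "Motif disruption by variant"
    ) +
    ggplot2::theme_minimal()
}

#' Paired allele-score plot
#'
#' Scatter of the best normalized motif score on the reference allele
#' against the alternate allele; points below the diagonal are disrupted
#' motifs, above it created ones.
#'
#' @param results A `motif_breakage` tibble.
#' @return A ggplot object.
#' @export
plot_allele_scores <- function(results) {
  ggplot2::ggplot(tibble::as_tibble(results), ggplot2::aes(
    x = .data$score_ref, y = .data$score_alt, color = .data$var_class
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "best match score, reference allele",
      y = "best match score, alternate allele",
      color = "variant class"
    ) +
    ggplot2::theme_minimal()
}
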