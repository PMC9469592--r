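#' Plot a correlation screen
#'
#' Effect-size versus significance view of a [screen_vs_score()] /
#' [screen_vs_age()] result: per-miRNA correlation estimate against
#' -log10 adjusted p, colored by direction, with the discovery cutoff
#' drawn as a dashed line.
#'
#' @param object A `mir_screen` tibble.
#' @param alpha Adjusted-p cutoff to draw (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mir_screen
#' @export
autoplot.mir_screen <- function(object, alpha = 0.05, ...) {
  dat <- dplyr::filter(object, .data$testable)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$estimate, y = -log10(.data$adj_p),
    colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(down = "#2166ac", up = "#b2182b")) +
    ggplot2::labs(
      x = sprintf("%s correlation", attr(object, "method")),
      y = expression(-log[10] ~ "adjusted p"),
      colour = "direction"
    ) +
    ggplot2::theme_minimal()
}

#' Plot composite miRNA scores by risk group
#'
#' Box plots of the per-sample composite score across Oncotype DX
#' DCIS risk groups, with the individual samples overlaid.
#'
#' @param object A `mirna_score` object.
#' @param clinical Clinical tibble supplying `risk_group` per sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirna_score
#' @export
autoplot.mirna_score <- function(object, clinical, ...) {
  dat <- score_with_groups(object, clinical)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$risk_group, y = .data$score, fill = .data$risk_group
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5) +
    ggplot2::labs(x = "Oncotype DX DCIS risk group", y = "composite miRNA score") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Scatter plot of composite miRNA score versus Oncotype DX score
#'
#' @param score A `mirna_score` object.
#' @param clinical Clinical tibble with `patient_id`, `dx_score` and
#'   `risk_group`.
#' @return A ggplot object with a least-squares trend line.
#' @export
plot_score_vs_dx <- function(score, clinical) {
  dat <- score_with_groups(score, clinical)
  dat$dx_score <- clinical$dx_score[match(dat$sample_id, clinical$patient_id)]
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$dx_score, y = .data$score, colour = .data$risk_group
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(
      ggplot2::aes(group = 1),
      method = "lm", formula = y ~ x, se = FALSE, colour = "grey30"
    ) +
    ggplot2::labs(
      x = "Oncotype DX DCIS score", y = "composite miRNA score",
      colour = "risk group"
    ) +
    ggplot2::theme_minimal()
}
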