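#' Plot subject-level eFAA by group
#'
#' Box-and-jitter plot of the scalar eFAA per group, the figure that shows
#' whether emotional modulation of FAA separates symptomatic mild-TBI
#' subjects from non-symptomatic ones and controls.
#'
#' @param object A `faa_scores` tibble (from [subject_scores()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faa_scores
#' @export
autoplot.faa_scores <- function(object, ...) {
  stopifnot(all(c("group", "efaa") %in% names(object)))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$efaa)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = NULL, y = "eFAA (ln-ratio)",
      title = "Emotional modulation of frontal alpha asymmetry by group"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ANOVA effect table
#'
#' Dot plot of generalized eta squared per effect, annotated with the
#' p values.
#'
#' @param object A `faa_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faa_anova
#' @export
autoplot.faa_anova <- function(object, ...) {
  t <- tidy(object)
  ggplot2::ggplot(t, ggplot2::aes(x = .data$ges, y = .data$effect)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("p = %.3g", .data$p_value)),
      vjust = -1, size = 3
    ) +
    ggplot2::labs(
      x = expression(eta[G]^2), y = NULL,
      title = sprintf("%s: effect sizes", object$design$dv)
    ) +
    ggplot2::theme_minimal()
}

#' Plot channel alpha power for a subject's alpha table
#'
#' Bar chart of alpha-band AUC per electrode and condition — the simple
#' channel-power view of the spectral stage.
#'
#' @param alpha_table Output of [condition_alpha_table()].
#' @return A ggplot object.
#' @export
plot_alpha_power <- function(alpha_table) {
  ggplot2::ggplot(
    alpha_table,
    ggplot2::aes(x = .data$electrode, y = .data$auc, fill = .data$emotion)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~relevance) +
    ggplot2::labs(
      x = NULL, y = expression("alpha AUC (" * mu * V^2 * ")"),
      title = "Alpha-band power by electrode and condition"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
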