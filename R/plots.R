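mode_scale <- function() {
  ggplot2::scale_colour_manual(
    values = c(sexual = "#c23b22", asexual = "#2b6cb0"),
    name = "mode"
  )
}

#' Plot per-species means of a gene-table statistic
#'
#' Mean and bootstrap-free normal-approximation 95% interval of a per-gene
#' statistic for every species, ordered by pair and coloured by
#' reproductive mode — the standard paired sexual/asexual panel.
#'
#' @param gene_table Gene table from [run_pipeline()] (needs `species`,
#'   `mode`, `pair_id` and the chosen column).
#' @param var Column to summarise (string), e.g. `"gc3"`, `"omega"`,
#'   `"cdc"`.
#' @return A ggplot object.
#' @export
plot_pair_means <- function(gene_table, var = "gc3") {
  d <- dplyr::summarise(
    dplyr::group_by(gene_table, .data$species, .data$mode, .data$pair_id),
    mean = mean(.data[[var]], na.rm = TRUE),
    se = stats::sd(.data[[var]], na.rm = TRUE) /
      sqrt(sum(!is.na(.data[[var]]))),
    .groups = "drop"
  )
  d <- dplyr::arrange(d, .data$pair_id, .data$mode)
  d$species <- factor(d$species, levels = d$species)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$species, y = .data$mean, colour = .data$mode
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - 1.96 * .data$se, ymax = .data$mean + 1.96 * .data$se
    )) +
    mode_scale() +
    ggplot2::labs(x = NULL, y = var) +
    ggplot2::theme_minimal()
}

#' @method autoplot gc_eq_fit
#' @export
autoplot.gc_eq_fit <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$terminal)
  d <- dplyr::arrange(d, .data$pair_id, .data$mode)
  d$branch <- factor(d$branch, levels = d$branch)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$branch, y = .data$theta, colour = .data$mode
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(
      yintercept = object$theta_stationary, linetype = "dashed",
      colour = "grey50"
    ) +
    mode_scale() +
    ggplot2::labs(
      x = NULL, y = "equilibrium GC3 (theta)",
      subtitle = "dashed line: stationary estimate"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the polymorphism summary
#'
#' Medians of the per-transcript variable-site proportion with their
#' bootstrap intervals, plus the proportion of transcripts containing SNPs,
#' per species.
#'
#' @param poly Output of [polymorphism_summary()] joined with tree metadata
#'   (columns `species`, `mode`, `pair_id` required).
#' @return A ggplot object.
#' @export
plot_polymorphism <- function(poly) {
  d <- dplyr::arrange(poly, .data$pair_id, .data$mode)
  d$species <- factor(d$species, levels = d$species)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$species, y = .data$median_var_prop, colour = .data$mode
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$var_prop_lo, ymax = .data$var_prop_hi
    )) +
    mode_scale() +
    ggplot2::labs(x = NULL, y = "variable sites per transcript (median)") +
    ggplot2::theme_minimal()
}

#' Plot the synonymous substitution spectrum
#'
#' Stacked proportions of weak-to-strong, strong-to-weak and
#' GC-conservative synonymous substitutions per terminal branch.
#'
#' @param spectrum A [classify_synonymous_substitutions()] result.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  d <- tidyr::pivot_longer(
    spectrum[, c("branch", "mode", "pair_id", "prop_ws", "prop_sw", "prop_cons")],
    dplyr::starts_with("prop_"),
    names_to = "category", values_to = "proportion"
  )
  d$category <- factor(d$category,
    levels = c("prop_ws", "prop_cons", "prop_sw"),
    labels = c("W->S", "conservative", "S->W")
  )
  d <- dplyr::arrange(d, .data$pair_id, .data$mode)
  d$branch <- factor(d$branch, levels = unique(d$branch))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$branch, y = .data$proportion, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", name = NULL) +
    ggplot2::labs(x = NULL, y = "proportion of synonymous substitutions") +
    ggplot2::theme_minimal()
}
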