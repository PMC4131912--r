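#' Boxplot of distance classes
#'
#' Reproduces the conventional view of within- and among-type divergence:
#' one box per distance class, distances expressed as percent nucleotide
#' change, whiskers at the Tukey bounds (Q1 - 1.5 IQR, Q3 + 1.5 IQR).
#'
#' @param object A `distance_classes` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot distance_classes
#' @export
autoplot.distance_classes <- function(object, ...) {
  df <- mutate(object$values, percent = 100 * .data$distance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$percent,
                                   fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.shape = 1, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(
      inter_type = "#c23b3b", intra_type = "#3f9e4d",
      intra_genomic = "#3b6fc2", overall = "grey40")) +
    ggplot2::labs(x = NULL, y = "patristic distance (% nucleotide change)") +
    ggplot2::theme_minimal()
}

#' Lineage-through-time plot of a GMYC fit
#'
#' Lineages accumulate slowly during the diversification phase and sharply
#' during within-species coalescence; the fitted threshold age marking the
#' shift is drawn as a dashed line.
#'
#' @param object A `gmyc_fit`.
#' @param ... Unused.
#' @return A ggplot (log lineage count against age, time running towards
#'   the present).
#' @method autoplot gmyc_fit
#' @export
autoplot.gmyc_fit <- function(object, ...) {
  df <- ltt_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = -.data$age, y = .data$lineages)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_vline(xintercept = -object$threshold, linetype = "dashed",
                        colour = "#c23b3b") +
    ggplot2::labs(x = "age (substitutions/site before present)",
                  y = "lineages",
                  title = sprintf("GMYC: %d entities, LR = %.2f (p = %.3g)",
                                  object$entities, object$LR,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot the ABGD plateau series
#'
#' MOTU count against prior intraspecific divergence (log scale); stable
#' plateaus appear as horizontal runs.
#'
#' @param series A `plateau_series` from [scan_priors()].
#' @return A ggplot.
#' @export
plot_plateaus <- function(series) {
  ggplot2::ggplot(series$entries,
                  ggplot2::aes(x = .data$prior, y = .data$motu_count)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "prior intraspecific divergence P",
                  y = "MOTU count") +
    ggplot2::theme_minimal()
}
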