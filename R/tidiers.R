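#' Tidy a GMYC fit into one row per delimited entity
#'
#' @param x A `gmyc_fit`.
#' @param ... Unused.
#' @return Tibble with `motu_id`, `n_tips` and `is_cluster` (entities with
#'   at least two tips are clusters; the rest are singletons).
#' @method tidy gmyc_fit
#' @export
tidy.gmyc_fit <- function(x, ...) {
  x$delimitation %>%
    count(.data$motu_id, name = "n_tips") %>%
    mutate(is_cluster = .data$n_tips >= 2) %>%
    arrange(as.integer(.data$motu_id))
}

#' One-row summary of a GMYC fit
#'
#' @param x A `gmyc_fit`.
#' @param ... Unused.
#' @return Tibble with the threshold age, rates, exponents,
#'   log-likelihoods, likelihood-ratio statistic and p-value, and
#'   cluster/entity counts.
#' @method glance gmyc_fit
#' @export
glance.gmyc_fit <- function(x, ...) {
  tibble(threshold = x$threshold, height = x$height, n_tips = x$n_tips,
         lambda_div = x$lambda_div, p_div = x$p_div,
         lambda_coal = x$lambda_coal, p_coal = x$p_coal,
         logL_gmyc = x$logL_gmyc, logL_null = x$logL_null,
         LR = x$LR, df = x$df, p_value = x$p_value,
         clusters = x$clusters, entities = x$entities)
}

#' Tidy distance classes into a long tibble
#'
#' @param x A `distance_classes` object.
#' @param ... Unused.
#' @return The per-class summary tibble (n, median, quartiles, Tukey
#'   bounds, percent columns).
#' @method tidy distance_classes
#' @export
tidy.distance_classes <- function(x, ...) {
  x$summary
}

#' Lineage-through-time table of a GMYC fit
#'
#' @param fit A `gmyc_fit`.
#' @return Tibble with event `age` and the number of `lineages` present
#'   just below each event, suitable for an LTT plot.
#' @export
ltt_table <- function(fit) {
  tibble(age = fit$event_ages,
         lineages = seq_along(fit$event_ages) + 1L)
}
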