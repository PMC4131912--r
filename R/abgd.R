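#' ABGD configuration
#'
#' Settings for automatic barcode gap discovery: the scanned range of prior
#' maximum intraspecific divergences, the number of log-spaced priors, and
#' the gap-detection sensitivity.
#'
#' @param p_min,p_max Range of prior intraspecific divergence (defaults
#'   0.001 and 0.1, substitutions/site).
#' @param steps Number of log-spaced priors scanned (default 10).
#' @param min_rel_width Minimum width of a qualifying gap relative to the
#'   local slope of ranked distances (default 1.5, the `X` parameter).
#' @param slope_window Number of preceding ranked-distance increments used
#'   to estimate the local slope (default 10).
#' @return A list of class `abgd_config`.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, steps = 10,
                        min_rel_width = 1.5, slope_window = 10) {
  stopifnot(p_min > 0, p_min < p_max, p_max < 1, steps >= 2,
            min_rel_width > 0, slope_window >= 1)
  structure(list(p_min = p_min, p_max = p_max, steps = steps,
                 min_rel_width = min_rel_width, slope_window = slope_window),
            class = "abgd_config")
}

#' Detect the barcode gap in a distance matrix
#'
#' Ranks pairwise distances, treats distances up to the prior `prior` as
#' presumed intraspecific, and looks for the first rank gap ending above the
#' prior whose width exceeds `min_rel_width` times the local slope (mean of
#' the preceding `slope_window` increments of the ranked distances) and is
#' at least as wide as the prior itself -- a species-level gap cannot be
#' narrower than the assumed intraspecific ceiling. The returned threshold
#' is the gap midpoint.
#'
#' @param dmat Distance matrix; non-finite (saturated) entries are ignored.
#' @param prior Prior maximum intraspecific divergence.
#' @param min_rel_width,slope_window Gap-detection settings, see
#'   [abgd_config()].
#' @return The threshold distance, or `NA_real_` when no qualifying gap
#'   exists.
#' @export
barcode_gap <- function(dmat, prior, min_rel_width = 1.5, slope_window = 10) {
  d <- sort(dmat[upper.tri(dmat)])
  d <- d[is.finite(d)]
  if (length(d) < 2) return(NA_real_)
  gaps <- diff(d)
  eps <- 10 * .Machine$double.eps * max(d, 1)
  for (i in seq_along(gaps)) {
    if (d[i + 1] <= prior) next
    slope <- if (i > 1) {
      mean(gaps[max(1, i - slope_window):(i - 1)])
    } else if (length(gaps) > 1) {
      # no increments precede the very first gap; fall back to the slope of
      # the following ranks so a smooth continuum is not split at its start
      mean(gaps[2:min(1 + slope_window, length(gaps))])
    } else {
      0
    }
    # a species-level gap must beat the local slope by the relative width
    # X and cannot be narrower than the assumed intraspecific ceiling P
    if (gaps[i] > max(min_rel_width * slope, prior, eps)) {
      return((d[i] + d[i + 1]) / 2)
    }
  }
  NA_real_
}

#' Partition sequences at a distance threshold
#'
#' MOTUs are the connected components of the graph joining every pair of
#' sequences closer than `threshold`, so a chain of small distances keeps
#' sequences together even when its endpoints are far apart.
#'
#' @param dmat Distance matrix.
#' @param threshold Distance threshold (pairs with `d < threshold` are
#'   linked).
#' @return A delimitation tibble with provenance `"abgd"`; MOTU ids are
#'   numbered by first appearance.
#' @export
partition_at <- function(dmat, threshold) {
  adj <- is.finite(dmat) & dmat < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  new_delimitation(tibble(seq_id = rownames(dmat),
                          motu_id = as.character(comp)),
                   provenance = "abgd")
}

#' Recursive barcode-gap partitioning at one prior
#'
#' Applies [barcode_gap()] and [partition_at()] to the full matrix, then
#' recurses within every resulting MOTU of at least three sequences until no
#' further qualifying gap is found. Entirely deterministic.
#'
#' @inheritParams barcode_gap
#' @return A delimitation tibble with provenance `"abgd"`.
#' @export
recursive_abgd <- function(dmat, prior, min_rel_width = 1.5,
                           slope_window = 10) {
  ids <- recursive_groups(dmat, prior, min_rel_width, slope_window)
  motu <- match(ids, unique(ids))
  new_delimitation(tibble(seq_id = rownames(dmat),
                          motu_id = as.character(motu)),
                   provenance = "abgd")
}

recursive_groups <- function(dmat, prior, min_rel_width, slope_window) {
  n <- nrow(dmat)
  if (n < 3) return(rep("1", n))
  thr <- barcode_gap(dmat, prior, min_rel_width, slope_window)
  if (is.na(thr)) return(rep("1", n))
  top <- partition_at(dmat, thr)
  # chaining can keep everything connected despite a rank gap; no split
  # means no further refinement is possible
  if (motu_count(top) == 1) return(rep("1", n))
  out <- top$motu_id
  for (g in unique(top$motu_id)) {
    members <- which(top$motu_id == g)
    if (length(members) >= 3) {
      sub <- recursive_groups(dmat[members, members, drop = FALSE],
                              prior, min_rel_width, slope_window)
      out[members] <- paste0(g, ".", sub)
    }
  }
  out
}

#' Scan the prior range and collect MOTU-count plateaus
#'
#' Runs [recursive_abgd()] once per log-spaced prior and groups contiguous
#' runs of equal MOTU count into plateaus, the stability signal used to pick
#' a species-level partition.
#'
#' @param dmat Distance matrix.
#' @param config An [abgd_config()].
#' @return A `plateau_series` object: list with `entries` (tibble of prior,
#'   motu_count and the delimitation), `plateaus` (tibble of motu_count,
#'   prior range and run length) and the configuration.
#' @export
scan_priors <- function(dmat, config = abgd_config()) {
  priors <- exp(seq(log(config$p_min), log(config$p_max),
                    length.out = config$steps))
  delims <- lapply(priors, function(p) {
    recursive_abgd(dmat, p, config$min_rel_width, config$slope_window)
  })
  entries <- tibble(prior = priors,
                    motu_count = vapply(delims, motu_count, 1L),
                    delimitation = delims)
  out <- list(entries = entries, plateaus = plateau_runs(entries),
              config = config)
  class(out) <- "plateau_series"
  out
}

plateau_runs <- function(entries) {
  r <- rle(entries$motu_count)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(motu_count = r$values,
         prior_min = entries$prior[starts],
         prior_max = entries$prior[ends],
         length = r$lengths)
}

#' @export
print.plateau_series <- function(x, ...) {
  cat("ABGD prior scan:", nrow(x$entries), "priors,",
      nrow(x$plateaus), "plateaus\n")
  print(x$plateaus)
  invisible(x)
}

#' Does a delimitation split clones of one individual across MOTUs?
#'
#' @param delim Delimitation tibble.
#' @param meta Metadata with `seq_id` and `individual_id`.
#' @return `TRUE` if any individual's sequences land in more than one MOTU.
#' @export
splits_individuals <- function(delim, meta) {
  ind <- meta$individual_id[match(delim$seq_id, meta$seq_id)]
  keep <- !is.na(ind)
  if (!any(keep)) return(FALSE)
  any(tapply(delim$motu_id[keep], ind[keep],
             function(x) length(unique(x))) > 1)
}

#' Select the species-level delimitation from a prior scan
#'
#' Delimitation hypotheses that assign clones of one individual to distinct
#' MOTUs are discarded. Among the survivors, plateaus (contiguous runs of
#' equal MOTU count) are ranked; a plateau is eligible when it spans more
#' than a factor of two in prior (stability under a doubling of what is
#' only an order-of-magnitude guess), with graceful fallbacks to two-point
#' runs and single points when nothing qualifies. The first eligible
#' plateau -- the one with the maximum MOTU count, ties broken toward the
#' smallest prior -- supplies the selected delimitation.
#'
#' @param series A `plateau_series` from [scan_priors()].
#' @param meta Optional metadata with `individual_id`, enabling the
#'   clone-consistency filter.
#' @return The selected delimitation; discarded entries and the chosen
#'   plateau are attached as attributes `"discarded"` and `"plateau"`. If
#'   every hypothesis is discarded, a single-MOTU fallback is returned with
#'   a warning.
#' @export
select_delimitation <- function(series, meta = NULL) {
  entries <- series$entries
  consistent <- if (is.null(meta) || !"individual_id" %in% names(meta)) {
    rep(TRUE, nrow(entries))
  } else {
    !vapply(entries$delimitation, splits_individuals, TRUE, meta = meta)
  }
  discarded <- entries[!consistent, c("prior", "motu_count")]
  surv <- entries[consistent, ]
  if (nrow(surv) == 0) {
    warn("all delimitation hypotheses split clones of one individual; falling back to a single MOTU")
    first <- entries$delimitation[[1]]
    fallback <- new_delimitation(tibble(seq_id = first$seq_id, motu_id = "1"),
                                 provenance = "abgd")
    attr(fallback, "discarded") <- discarded
    return(fallback)
  }
  runs <- plateau_runs(surv)
  # a species-level plateau should tolerate at least a doubling of the
  # prior, which is only an order-of-magnitude guess; fall back to shorter
  # runs when nothing qualifies
  span <- runs$prior_max / runs$prior_min
  eligible <- if (any(span > 2)) {
    runs[span > 2, ]
  } else if (any(runs$length >= 2)) {
    runs[runs$length >= 2, ]
  } else {
    runs
  }
  best <- eligible[order(-eligible$motu_count, eligible$prior_min), ][1, ]
  pick <- which(surv$motu_count == best$motu_count &
                  surv$prior >= best$prior_min & surv$prior <= best$prior_max)[1]
  out <- surv$delimitation[[pick]]
  attr(out, "discarded") <- discarded
  attr(out, "plateau") <- best
  attr(out, "prior") <- surv$prior[pick]
  out
}

#' Run the full ABGD procedure on a distance matrix
#'
#' Convenience wrapper: [scan_priors()] then [select_delimitation()].
#'
#' @inheritParams scan_priors
#' @inheritParams select_delimitation
#' @return The selected delimitation, with the `plateau_series` attached as
#'   attribute `"series"`.
#' @export
abgd_delimit <- function(dmat, meta = NULL, config = abgd_config()) {
  series <- scan_priors(dmat, config)
  out <- select_delimitation(series, meta)
  attr(out, "series") <- series
  out
}
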