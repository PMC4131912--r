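#' Kimura two-parameter distance matrix
#'
#' Computes pairwise K80 distances over the aligned block,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with transition proportion
#' `P` and transversion proportion `Q` counted over pairwise-complete sites
#' (gaps and ambiguity codes excluded pair by pair). Saturated pairs, where
#' a log argument is non-positive, are set to `Inf` and flagged.
#'
#' @param aln Aligned sequence table (>= 2 records).
#' @return A symmetric numeric matrix with seq_id dimnames; saturated pairs
#'   are listed in the `"saturated"` attribute.
#' @export
k80_matrix <- function(aln) {
  if (nrow(aln) < 2) abort("need at least 2 sequences for a distance matrix")
  m <- seq_matrix(aln)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  comparable <- ok %*% t(ok)
  if (any(comparable[upper.tri(comparable)] == 0)) {
    idx <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)[1, ]
    abort(paste0("no comparable sites between ", aln$seq_id[idx[1]],
                 " and ", aln$seq_id[idx[2]]))
  }
  bin <- ape::as.DNAbin(m)
  d <- suppressWarnings(
    ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE,
                  as.matrix = TRUE)
  )
  dimnames(d) <- list(aln$seq_id, aln$seq_id)
  sat <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(sat) > 0) {
    warn(paste0(nrow(sat), " saturated pair(s) set to Inf"))
    d[!is.finite(d)] <- Inf
    diag(d) <- 0
  }
  attr(d, "saturated") <- tibble(
    seq_id_1 = rownames(d)[sat[, 1]],
    seq_id_2 = colnames(d)[sat[, 2]]
  )
  d
}

#' Patristic distance matrix from a tree
#'
#' Sums branch lengths along the unique tip-to-tip path of a phylogram.
#' Negative branch lengths (an artifact of some distance-based builders)
#' are clamped to zero with a warning by default.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param clamp_negative Clamp negative branch lengths to zero (default);
#'   if `FALSE`, negative lengths abort.
#' @return A symmetric numeric matrix with tip-label dimnames.
#' @export
patristic_matrix <- function(tree, clamp_negative = TRUE) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) {
    if (!clamp_negative) abort("tree has negative branch lengths")
    warn("negative branch lengths clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  as.matrix(cophenetic(tree))
}

distance_pairs <- function(dmat) {
  labs <- rownames(dmat)
  idx <- which(upper.tri(dmat), arr.ind = TRUE)
  tibble(seq_id_1 = labs[idx[, 1]], seq_id_2 = labs[idx[, 2]],
         distance = dmat[idx])
}

#' Partition pairwise distances into the standard classes
#'
#' Each unordered pair of sequences is labelled `intra_genomic` (clones of
#' one individual), `intra_type` (same MOTU, different individuals),
#' or `inter_type` (different MOTUs); `overall` collects every pair. When no
#' delimitation is supplied only `overall` and `intra_genomic` are computed.
#' Non-finite (saturated) distances are excluded from summaries with a
#' warning.
#'
#' @param dmat Distance matrix (K80 or patristic).
#' @param meta Metadata table with `seq_id` and `individual_id`.
#' @param delim Optional delimitation tibble defining the types/MOTUs.
#' @return A `distance_classes` object: list with `values` (long tibble of
#'   class and distance) and `summary` (per-class n, median, quartiles, IQR
#'   and Tukey outlier bounds; `*_pct` columns are percent nucleotide
#'   change, i.e. distance x 100).
#' @export
classify_distances <- function(dmat, meta, delim = NULL) {
  pairs <- distance_pairs(dmat)
  if (any(!is.finite(pairs$distance))) {
    warn("non-finite distances excluded from class summaries")
    pairs <- pairs[is.finite(pairs$distance), ]
  }
  ind <- meta$individual_id[match(pairs$seq_id_1, meta$seq_id)]
  ind2 <- meta$individual_id[match(pairs$seq_id_2, meta$seq_id)]
  same_ind <- !is.na(ind) & !is.na(ind2) & ind == ind2

  cls <- rep(NA_character_, nrow(pairs))
  cls[same_ind] <- "intra_genomic"
  if (!is.null(delim)) {
    m1 <- delim$motu_id[match(pairs$seq_id_1, delim$seq_id)]
    m2 <- delim$motu_id[match(pairs$seq_id_2, delim$seq_id)]
    cls[is.na(cls) & !is.na(m1) & !is.na(m2) & m1 == m2] <- "intra_type"
    cls[is.na(cls) & !is.na(m1) & !is.na(m2) & m1 != m2] <- "inter_type"
  }
  values <- bind_rows(
    tibble(class = "overall", distance = pairs$distance),
    tibble(class = cls, distance = pairs$distance)[!is.na(cls), ]
  )
  out <- list(values = values, summary = summarise_classes(values))
  class(out) <- "distance_classes"
  out
}

summarise_classes <- function(values) {
  all_classes <- c("inter_type", "intra_type", "intra_genomic", "overall")
  values %>%
    group_by(.data$class) %>%
    summarise(
      n = dplyr::n(),
      median = median(.data$distance),
      q1 = quantile(.data$distance, 0.25, names = FALSE),
      q3 = quantile(.data$distance, 0.75, names = FALSE),
      .groups = "drop"
    ) %>%
    mutate(
      iqr = .data$q3 - .data$q1,
      lower_bound = .data$q1 - 1.5 * .data$iqr,
      upper_bound = .data$q3 + 1.5 * .data$iqr,
      median_pct = 100 * .data$median
    ) %>%
    bind_rows(tibble(class = setdiff(all_classes, unique(values$class)),
                     n = 0L)) %>%
    arrange(match(.data$class, all_classes))
}

class_values <- function(classes, which) {
  classes$values$distance[classes$values$class == which]
}

#' Barcode-gap statistics for classified distances
#'
#' Reports the distance gap `min(inter_type) - max(intra)`, where `intra`
#' pools intra-type and intra-genomic distances, together with per-class
#' medians and an overlap flag. An empty class leaves the gap undefined.
#'
#' @param classes A `distance_classes` object.
#' @return A one-row tibble with `gap`, `gap_pct`, `overlap`, per-class
#'   medians and a `defined` flag.
#' @export
gap_statistics <- function(classes) {
  inter <- class_values(classes, "inter_type")
  intra <- c(class_values(classes, "intra_type"),
             class_values(classes, "intra_genomic"))
  defined <- length(inter) > 0 && length(intra) > 0
  gap <- if (defined) min(inter) - max(intra) else NA_real_
  tibble(
    defined = defined,
    gap = gap,
    gap_pct = 100 * gap,
    overlap = if (defined) min(inter) < max(intra) else NA,
    median_inter = if (length(inter)) median(inter) else NA_real_,
    median_intra = if (length(intra)) median(intra) else NA_real_
  )
}

#' Compare two distance distributions
#'
#' Two-sample Kolmogorov-Smirnov and Mann-Whitney tests (two-sided). The
#' Mann-Whitney test is exact when both samples have eight or fewer values
#' and tie-free otherwise uses the normal approximation with tie
#' correction. Samples below `min_n` give an inconclusive report with no
#' p-values, echoing how sparsely sampled genetic types must be handled.
#'
#' @param a,b Numeric distance vectors.
#' @param min_n Minimum class size for testing (default 3).
#' @return A one-row tibble with `ks_stat`, `ks_p`, `mw_u`, `mw_p` and a
#'   `conclusive` flag.
#' @export
compare_distributions <- function(a, b, min_n = 3) {
  if (length(a) < min_n || length(b) < min_n) {
    return(tibble(conclusive = FALSE, n_a = length(a), n_b = length(b),
                  ks_stat = NA_real_, ks_p = NA_real_,
                  mw_u = NA_real_, mw_p = NA_real_))
  }
  ks <- suppressWarnings(ks.test(a, b))
  exact <- length(a) <= 8 && length(b) <= 8
  mw <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  tibble(conclusive = TRUE, n_a = length(a), n_b = length(b),
         ks_stat = unname(ks$statistic), ks_p = ks$p.value,
         mw_u = unname(mw$statistic), mw_p = mw$p.value)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Studier-Keppler neighbor joining; a fallback phylogram builder for when
#' no externally estimated maximum-likelihood tree is supplied. Negative
#' branch lengths are clamped to zero.
#'
#' @param dmat Symmetric distance matrix with labels.
#' @return An `ape::phylo` phylogram.
#' @export
nj_tree <- function(dmat) {
  n <- nrow(dmat)
  if (n < 2) abort("need at least 2 taxa")
  if (n == 2) return(two_tip_tree(rownames(dmat), dmat[1, 2]))
  tree <- ape::nj(as.dist(dmat))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' UPGMA ultrametric tree from a distance matrix
#'
#' Average-linkage clustering converted to an ultrametric chronogram whose
#' tip-to-tip path lengths approximate the input distances; a fallback for
#' when no externally dated chronogram is supplied.
#'
#' @param dmat Symmetric distance matrix with labels.
#' @return An ultrametric `ape::phylo` tree.
#' @export
upgma_chronogram <- function(dmat) {
  n <- nrow(dmat)
  if (n < 2) abort("need at least 2 taxa")
  if (n == 2) return(two_tip_tree(rownames(dmat), dmat[1, 2]))
  ape::as.phylo(hclust(as.dist(dmat), method = "average"))
}

two_tip_tree <- function(labels, d) {
  ape::read.tree(text = sprintf("(%s:%g,%s:%g);", labels[1], d / 2,
                                labels[2], d / 2))
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dmat Distance matrix with labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dmat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dmat)), con)
  for (i in seq_len(nrow(dmat))) {
    writeLines(paste(c(formatC(rownames(dmat)[i], width = -10),
                       formatC(dmat[i, ], format = "f", digits = 10)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path Path to a PHYLIP square distance file.
#' @return A symmetric numeric matrix with labels.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labs <- vapply(parts, `[[`, "", 1)
  d <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(d) <- list(labs, labs)
  d
}
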