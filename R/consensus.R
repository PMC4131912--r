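#' Merge MOTUs that split clones of one individual
#'
#' rDNA copies (clones) sequenced from a single individual belong to one
#' organism, so MOTUs sharing an individual are iteratively unioned until no
#' individual spans two MOTUs. Merging only coarsens the partition. The
#' merged MOTU keeps the smallest constituent id.
#'
#' @param delim Delimitation tibble.
#' @param meta Metadata with `seq_id` and `individual_id`.
#' @return A delimitation with provenance `"consensus"`.
#' @export
merge_clone_splits <- function(delim, meta) {
  motus <- unique(delim$motu_id)
  parent <- setNames(seq_along(motus), motus)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ind <- meta$individual_id[match(delim$seq_id, meta$seq_id)]
  for (one_ind in unique(ind[!is.na(ind)])) {
    ms <- unique(delim$motu_id[!is.na(ind) & ind == one_ind])
    if (length(ms) > 1) {
      roots <- vapply(match(ms, motus), find, 1L)
      for (r in roots[-1]) parent[r] <- min(roots)
    }
  }
  root_of <- vapply(match(delim$motu_id, motus), find, 1L)
  # deterministic id: smallest constituent motu_id of each merged group
  new_id <- vapply(split(delim$motu_id, root_of), function(x) min(x),
                   "")[as.character(root_of)]
  out <- new_delimitation(tibble(seq_id = delim$seq_id, motu_id = new_id),
                          provenance = "consensus")
  stopifnot(!splits_individuals(out, meta))
  out
}

#' Screen singleton MOTUs for sequencing artifacts
#'
#' Isolated sequences that GMYC or ABGD set apart are often old, short or
#' error-ridden submissions rather than genuine species. A singleton MOTU is
#' flagged suspect when its sequence is shorter than `min_length`, was
#' submitted before `year_cutoff`, or when more than half of its mismatches
#' against the majority consensus of the nearest MOTU fall in the first
#' quarter of the alignment columns (the 5'-end error signature). Flags are
#' advisory; with `apply_screen = TRUE` suspect singletons are merged into
#' their nearest MOTU.
#'
#' @param delim Delimitation tibble.
#' @param meta Metadata with `seq_id`, optionally `year`.
#' @param aln Aligned sequence table covering the delimited sequences.
#' @param min_length Minimum acceptable sequence length in bp (default 500).
#' @param year_cutoff Singletons submitted before this year are flagged
#'   (default 2000).
#' @param min_mismatches Positional criterion needs at least this many
#'   mismatches to be meaningful (default 4).
#' @param apply_screen Merge suspect singletons into their nearest MOTU.
#' @return A list with `flags` (tibble: seq_id, motu_id, reasons, nearest
#'   MOTU) and `delimitation` (unchanged unless `apply_screen`).
#' @export
screen_singletons <- function(delim, meta, aln, min_length = 500,
                              year_cutoff = 2000, min_mismatches = 4,
                              apply_screen = FALSE) {
  sizes <- table(delim$motu_id)
  singles <- names(sizes)[sizes == 1]
  m <- seq_matrix(aln)
  empty <- tibble(seq_id = character(0), motu_id = character(0),
                  nearest_motu = character(0), suspect = logical(0),
                  reasons = character(0))
  flags <- bind_rows(empty, purrr::map_dfr(singles, function(motu) {
    sid <- delim$seq_id[delim$motu_id == motu]
    reasons <- character(0)
    len <- nongap_length(aln$bases[aln$seq_id == sid])
    if (length(len) == 1 && len < min_length) reasons <- c(reasons, "short")
    yr <- meta$year[match(sid, meta$seq_id)]
    if (length(yr) == 1 && !is.na(yr) && yr < year_cutoff) {
      reasons <- c(reasons, "old")
    }
    near <- nearest_motu(sid, delim, aln)
    if (!is.na(near) && sid %in% rownames(m)) {
      cons <- motu_consensus(m, delim$seq_id[delim$motu_id == near])
      pos <- mismatch_positions(m[sid, ], cons)
      if (length(pos) >= min_mismatches &&
          mean(pos <= ncol(m) / 4) > 0.5) {
        reasons <- c(reasons, "five_prime_errors")
      }
    }
    tibble(seq_id = sid, motu_id = motu, nearest_motu = near,
           suspect = length(reasons) > 0,
           reasons = paste(reasons, collapse = ";"))
  }))
  out <- delim
  if (apply_screen && nrow(flags) > 0) {
    for (i in which(flags$suspect & !is.na(flags$nearest_motu))) {
      out$motu_id[out$seq_id == flags$seq_id[i]] <- flags$nearest_motu[i]
    }
    out <- new_delimitation(out, provenance = "consensus")
  }
  list(flags = flags, delimitation = out)
}

# nearest MOTU by mean p-distance over shared non-gap columns
nearest_motu <- function(sid, delim, aln) {
  m <- seq_matrix(aln)
  if (!sid %in% rownames(m)) return(NA_character_)
  others <- delim[delim$seq_id != sid & delim$seq_id %in% rownames(m), ]
  if (nrow(others) == 0) return(NA_character_)
  x <- m[sid, ]
  pd <- vapply(others$seq_id, function(o) {
    y <- m[o, ]
    ok <- x != "-" & y != "-"
    if (!any(ok)) return(NA_real_)
    mean(x[ok] != y[ok])
  }, 0)
  means <- tapply(pd, others$motu_id, mean, na.rm = TRUE)
  names(means)[which.min(means)]
}

motu_consensus <- function(m, seq_ids) {
  seq_ids <- intersect(seq_ids, rownames(m))
  sub <- m[seq_ids, , drop = FALSE]
  apply(sub, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    names(sort(table(col), decreasing = TRUE))[1]
  })
}

mismatch_positions <- function(x, cons) {
  ok <- x != "-" & cons != "-"
  which(ok & x != cons)
}

#' Cross-validate a delimitation against patristic distance classes
#'
#' Recomputes the distance classes under the candidate delimitation and
#' issues a verdict, evaluated in order: `inconclusive`
#' (inter- or intra-type class below `min_n`), `invalid_low_inter` (median
#' inter-type distance no larger than the intra-genomic maximum, i.e.
#' improbably low between putative species), `invalid_overlap` (intra- and
#' inter-type distances overlap), else `validated`.
#'
#' @param delim Candidate delimitation.
#' @param dmat Patristic distance matrix over the same sequences.
#' @param meta Metadata with `individual_id`.
#' @param min_n Minimum class size for a conclusive verdict (default 3).
#' @return A `validation_verdict`: list with `verdict`, the
#'   `distance_classes` evidence, the gap report and the KS/Mann-Whitney
#'   comparison of intra vs inter distances.
#' @export
crossvalidate <- function(delim, dmat, meta, min_n = 3) {
  keep <- intersect(rownames(dmat), delim$seq_id)
  classes <- classify_distances(dmat[keep, keep, drop = FALSE], meta, delim)
  inter <- class_values(classes, "inter_type")
  intra <- class_values(classes, "intra_type")
  intra_g <- class_values(classes, "intra_genomic")
  gap <- gap_statistics(classes)
  tests <- compare_distributions(c(intra, intra_g), inter, min_n)

  verdict <- if (length(inter) < min_n || length(c(intra, intra_g)) < min_n) {
    "inconclusive"
  } else if (length(intra_g) > 0 && median(inter) <= max(intra_g)) {
    "invalid_low_inter"
  } else if (min(inter) < max(c(intra, intra_g))) {
    "invalid_overlap"
  } else {
    "validated"
  }
  out <- list(verdict = verdict, classes = classes, gap = gap, tests = tests)
  class(out) <- "validation_verdict"
  out
}

#' @export
print.validation_verdict <- function(x, ...) {
  cat("Patristic cross-validation verdict:", x$verdict, "\n")
  print(x$gap)
  invisible(x)
}

#' Congruence between two delimitations
#'
#' Counts MOTUs of `a` whose member sets are exactly reproduced in `b`
#' (after restricting both to the shared sequences, which is reported), the
#' fraction relative to `a`'s MOTU count, and the adjusted Rand index.
#'
#' @param a,b Delimitation tibbles.
#' @return One-row tibble with `identical_motus`, `fraction`, `ari`,
#'   MOTU counts and the shared sequence count.
#' @export
congruence <- function(a, b) {
  common <- intersect(a$seq_id, b$seq_id)
  if (length(common) == 0) abort("delimitations cover disjoint sequence sets")
  a2 <- a[a$seq_id %in% common, ]
  b2 <- b[b$seq_id %in% common, ]
  sets_a <- motu_sets(a2)
  sets_b <- motu_sets(b2)
  ident <- sum(vapply(sets_a, function(s) {
    any(vapply(sets_b, identical, TRUE, x = s))
  }, TRUE))
  tibble(identical_motus = ident,
         motus_a = length(sets_a), motus_b = length(sets_b),
         fraction = ident / length(sets_a),
         ari = delimitation_ari(a2, b2),
         n_shared = length(common))
}

#' Assemble the consensus species table
#'
#' One row per (morpho-species, candidate species): the MOTU each method
#' assigns, the cross-validation verdicts, and a consensus status --
#' `congruent-species` when ABGD and GMYC delimit the identical sequence
#' set and the validated verdict supports it, `ambiguous` when evidence is
#' inconclusive, `method-conflict` otherwise.
#'
#' @param literature Optional literature delimitation (may be `NULL`).
#' @param abgd ABGD delimitation.
#' @param gmyc GMYC delimitation.
#' @param verdicts Named list of `validation_verdict`s, with elements
#'   `abgd` and `gmyc` (and optionally `literature`).
#' @param meta Metadata with `seq_id` and `morphospecies`.
#' @return A tibble, one row per ABGD-or-GMYC MOTU within each
#'   morpho-species, with membership, verdicts and `status`.
#' @export
build_species_table <- function(literature = NULL, abgd, gmyc, verdicts,
                                meta) {
  common <- intersect(abgd$seq_id, gmyc$seq_id)
  a2 <- abgd[abgd$seq_id %in% common, ]
  g2 <- gmyc[gmyc$seq_id %in% common, ]
  sets_g <- motu_sets(g2)
  verdict_of <- function(which) {
    if (!is.null(verdicts[[which]])) verdicts[[which]]$verdict else NA_character_
  }
  rows <- purrr::map_dfr(names(motu_sets(a2)), function(motu) {
    members <- sort(a2$seq_id[a2$motu_id == motu])
    matched <- any(vapply(sets_g, identical, TRUE, x = members))
    sp <- unique(meta$morphospecies[match(members, meta$seq_id)])
    lit <- if (!is.null(literature)) {
      paste(sort(unique(literature$motu_id[match(members, literature$seq_id)])),
            collapse = "+")
    } else {
      NA_character_
    }
    status <- if (matched && identical(verdict_of("abgd"), "validated") &&
                  identical(verdict_of("gmyc"), "validated")) {
      "congruent-species"
    } else if (identical(verdict_of("abgd"), "inconclusive") ||
               identical(verdict_of("gmyc"), "inconclusive")) {
      "ambiguous"
    } else {
      "method-conflict"
    }
    tibble(morphospecies = paste(sp[!is.na(sp)], collapse = "+"),
           abgd_motu = motu,
           gmyc_match = matched,
           literature_motu = lit,
           n_sequences = length(members),
           abgd_verdict = verdict_of("abgd"),
           gmyc_verdict = verdict_of("gmyc"),
           status = status)
  })
  rows
}
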