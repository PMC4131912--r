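#' Read a FASTA file into a sequence table
#'
#' Sequences are returned as a tibble, one row per record, in file order.
#' The header up to the first whitespace is taken as the sequence id.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id`, `bases` (IUPAC string, gaps kept)
#'   and `length_bp` (number of non-gap characters).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence ids in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  bases <- toupper(as.character(set))
  tibble(seq_id = ids, bases = unname(bases), length_bp = nongap_length(bases))
}

#' Write a sequence table to FASTA
#'
#' @param seqs Sequence table with `seq_id` and `bases` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("seq_id", "bases") %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(seqs$bases, seqs$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

nongap_length <- function(bases) {
  nchar(gsub("-", "", bases, fixed = TRUE))
}

#' Attach specimen metadata to a sequence table
#'
#' Joins a metadata table (columns `seq_id`, `morphospecies`,
#' `individual_id`, and optionally `clone_id`, `type_label`, `year`) onto the
#' sequence table. Clone ids must nest within individuals, and individuals
#' within morpho-species; violations abort because every downstream
#' clone-consistency rule relies on that nesting.
#'
#' @param seqs Sequence table from [read_fasta()].
#' @param meta Metadata data frame with at least `seq_id`.
#' @return The sequence table with metadata columns added; records absent
#'   from `meta` keep `NA` fields and are flagged in the `has_metadata`
#'   column.
#' @export
join_metadata <- function(seqs, meta) {
  meta <- as_tibble(meta)
  if (!"seq_id" %in% names(meta)) abort("metadata must have a seq_id column")
  if (anyDuplicated(meta$seq_id)) abort("metadata seq_id values must be unique")
  for (col in c("morphospecies", "individual_id", "clone_id", "type_label")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  if (!"year" %in% names(meta)) meta$year <- NA_integer_

  orphan <- setdiff(meta$seq_id, seqs$seq_id)
  if (length(orphan) > 0) {
    warn(paste0("metadata rows without a matching sequence: ",
                paste(orphan, collapse = ", ")))
  }
  check_nesting(meta, "individual_id", "morphospecies")
  check_nesting(meta, "clone_id", "individual_id")

  out <- left_join(seqs,
                   select(meta, "seq_id", "morphospecies", "individual_id",
                          "clone_id", "type_label", "year"),
                   by = "seq_id")
  out$has_metadata <- out$seq_id %in% meta$seq_id
  out
}

check_nesting <- function(meta, child, parent) {
  m <- meta[!is.na(meta[[child]]), c(child, parent)]
  if (nrow(m) == 0) return(invisible(NULL))
  bad <- tapply(m[[parent]], m[[child]], function(x) length(unique(x[!is.na(x)])))
  bad <- names(bad)[!is.na(bad) & bad > 1]
  if (length(bad) > 0) {
    abort(paste0("each ", child, " must map to one ", parent,
                 "; violated by: ", paste(bad, collapse = ", ")))
  }
  invisible(NULL)
}

aln_width <- function(aln) {
  w <- unique(nchar(aln$bases))
  if (length(w) > 1) abort("alignment rows have unequal gapped lengths")
  if (length(w) == 0) 0L else w
}

seq_matrix <- function(aln) {
  if (nrow(aln) == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  m <- do.call(rbind, strsplit(toupper(aln$bases), ""))
  rownames(m) <- aln$seq_id
  m
}

matrix_to_aln <- function(m, template) {
  out <- template
  out$bases <- if (nrow(m) == 0) {
    character(0)
  } else {
    unname(apply(m, 1, paste0, collapse = ""))
  }
  out$length_bp <- nongap_length(out$bases)
  out
}

#' Extract a homologous alignment block
#'
#' Cuts the alignment to columns `[start, end)` (0-based, half-open) and
#' drops records whose non-gap coverage of the block falls below
#' `min_coverage`. The primer positions bounding the analysis block are a
#' configuration item; [locate_primer()] helps find them.
#'
#' @param aln Aligned sequence table (equal gapped lengths).
#' @param start,end 0-based half-open column interval.
#' @param min_coverage Minimum non-gap fraction a record must have inside
#'   the block to be retained (default 0.95).
#' @return The sub-alignment; dropped records are reported in the
#'   `"dropped"` attribute (a tibble with seq_id and coverage).
#' @export
extract_block <- function(aln, start, end, min_coverage = 0.95) {
  w <- aln_width(aln)
  if (!(start >= 0 && start < end && end <= w)) {
    abort(paste0("block [", start, ",", end, ") outside alignment of width ", w))
  }
  m <- seq_matrix(aln)[, (start + 1):end, drop = FALSE]
  cov <- rowMeans(m != "-")
  keep <- cov >= min_coverage
  out <- matrix_to_aln(m[keep, , drop = FALSE], aln[keep, , drop = FALSE])
  attr(out, "block") <- c(start = start, end = end)
  attr(out, "dropped") <- tibble(seq_id = aln$seq_id[!keep],
                                 coverage = unname(cov[!keep]))
  out
}

#' Locate a primer motif in an alignment
#'
#' Searches the consensus-free, per-sequence ungapped context for `motif`
#' allowing up to `max_mismatch` mismatches, and reports the most common
#' alignment column where the motif starts.
#'
#' @param aln Aligned sequence table.
#' @param motif Primer sequence (5'->3', IUPAC ACGT only).
#' @param max_mismatch Allowed mismatches (default 1).
#' @return 0-based alignment column of the motif start, or `NA` if not found.
#' @export
locate_primer <- function(aln, motif, max_mismatch = 1) {
  m <- seq_matrix(aln)
  motif <- strsplit(toupper(motif), "")[[1]]
  k <- length(motif)
  hits <- integer(0)
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    cols <- which(row != "-")
    if (length(cols) < k) next
    s <- row[cols]
    for (i in seq_len(length(s) - k + 1)) {
      if (sum(s[i:(i + k - 1)] != motif) <= max_mismatch) {
        hits <- c(hits, cols[i] - 1L)
        break
      }
    }
  }
  if (length(hits) == 0) return(NA_integer_)
  as.integer(names(sort(table(hits), decreasing = TRUE))[1])
}

#' Collapse identical sequences to unique representatives
#'
#' Identical base strings (uppercased, compared literally including
#' ambiguity codes, over the current alignment columns) are pooled and the
#' first-seen member is retained as representative. Downstream partitions
#' computed on representatives can be re-expanded to all members with
#' [expand_delimitation()].
#'
#' @param aln Aligned sequence table.
#' @return A list with `alignment` (representatives only) and `map`
#'   (tibble `representative_id`, `member_id`).
#' @export
dereplicate <- function(aln) {
  key <- toupper(aln$bases)
  rep_id <- aln$seq_id[match(key, key)]
  map <- tibble(representative_id = rep_id, member_id = aln$seq_id)
  list(alignment = aln[aln$seq_id %in% unique(rep_id) &
                         !duplicated(key), , drop = FALSE],
       map = map)
}

#' Re-expand a delimitation of representatives to all pooled members
#'
#' @param delim Delimitation tibble (`seq_id`, `motu_id`) over
#'   representatives.
#' @param map Dereplication map from [dereplicate()].
#' @return Delimitation covering every member sequence.
#' @export
expand_delimitation <- function(delim, map) {
  out <- left_join(map, delim, by = c(representative_id = "seq_id"))
  new_delimitation(tibble(seq_id = out$member_id, motu_id = out$motu_id),
                   provenance = delimitation_provenance(delim))
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @param known_tips Optional character vector of valid tip labels; tips
#'   outside it abort with the offending labels.
#' @param tol Relative ultrametricity tolerance: the root-to-tip spread must
#'   not exceed `tol` times the tree height for the tree to be flagged
#'   ultrametric.
#' @return An `ape::phylo` tree with an `"ultrametric"` attribute.
#' @export
read_newick <- function(path, known_tips = NULL, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("could not parse Newick in ", path))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (!is.null(known_tips)) {
    unknown <- setdiff(tree$tip.label, known_tips)
    if (length(unknown) > 0) {
      abort(paste0("tree tips not present in metadata: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  attr(tree, "ultrametric") <- tree_is_ultrametric(tree, tol)
  tree
}

#' Write a tree to Newick
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

tree_is_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (h == 0) return(TRUE)
  (max(depths) - min(depths)) <= tol * h
}

node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}
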