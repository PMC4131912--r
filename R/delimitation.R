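#' Construct a delimitation
#'
#' A delimitation is a tibble assigning every sequence id to a molecular
#' operational taxonomic unit (MOTU), with a provenance tag recording which
#' method produced it.
#'
#' @param x Data frame with columns `seq_id` and `motu_id`.
#' @param provenance One of `"literature"`, `"abgd"`, `"gmyc"`,
#'   `"consensus"`, or `"truth"` (synthetic data).
#' @return A `delimitation` tibble.
#' @export
new_delimitation <- function(x, provenance = "literature") {
  x <- as_tibble(x)[, c("seq_id", "motu_id")]
  if (anyDuplicated(x$seq_id)) abort("delimitation assigns a seq_id twice")
  x$motu_id <- as.character(x$motu_id)
  attr(x, "provenance") <- provenance
  class(x) <- c("delimitation", class(x))
  x
}

#' @export
print.delimitation <- function(x, ...) {
  cat("Delimitation (", delimitation_provenance(x), "): ",
      motu_count(x), " MOTUs over ", nrow(x), " sequences\n", sep = "")
  NextMethod()
}

delimitation_provenance <- function(delim) {
  p <- attr(delim, "provenance")
  if (is.null(p)) "literature" else p
}

#' Number of MOTUs in a delimitation
#'
#' @param delim A delimitation tibble.
#' @return Integer count of distinct MOTU ids.
#' @export
motu_count <- function(delim) {
  length(unique(delim$motu_id))
}

#' Members of each MOTU as a named list of sequence-id sets
#' @noRd
motu_sets <- function(delim) {
  lapply(split(delim$seq_id, delim$motu_id), sort)
}

#' Adjusted Rand index between two delimitations
#'
#' @param a,b Delimitation tibbles over the same sequences.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
delimitation_ari <- function(a, b) {
  common <- intersect(a$seq_id, b$seq_id)
  if (length(common) == 0) abort("delimitations share no sequences")
  la <- a$motu_id[match(common, a$seq_id)]
  lb <- b$motu_id[match(common, b$seq_id)]
  mclust::adjustedRandIndex(la, lb)
}
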