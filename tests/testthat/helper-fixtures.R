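# fixtures are built in code so the repository stays text-only

tiny_aln <- function(...) {
  seqs <- c(...)
  tibble::tibble(seq_id = names(seqs), bases = unname(toupper(seqs)),
                 length_bp = nchar(gsub("-", "", seqs, fixed = TRUE)))
}

# two sequences with exactly `n_ts` transitions and `n_tv` transversions
# over `n_sites` comparable sites (A<->G transitions, A<->T transversions)
counted_pair_aln <- function(n_sites, n_ts, n_tv) {
  a <- rep("A", n_sites)
  b <- rep("A", n_sites)
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "T"
  tiny_aln(s1 = paste0(a, collapse = ""), s2 = paste0(b, collapse = ""))
}

k80_closed_form <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# block distance matrix: clusters of given sizes, fixed within- and
# between-cluster distances
block_matrix <- function(sizes, d_within, d_between,
                         labels = NULL) {
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  d <- matrix(d_between, n, n)
  for (g in seq_along(sizes)) {
    idx <- which(grp == g)
    d[idx, idx] <- d_within
  }
  diag(d) <- 0
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  dimnames(d) <- list(labels, labels)
  d
}

# independent patristic oracle: per-pair path sum over ape::nodepath
patristic_bruteforce <- function(tree) {
  n <- length(tree$tip.label)
  edge_len <- numeric(max(tree$edge))
  edge_len[tree$edge[, 2]] <- tree$edge.length
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      path <- ape::nodepath(tree, i, j)
      # nodes on the path except the shallowest (the LCA) contribute their
      # parent edge; the LCA is the node with minimal depth on the path
      depths <- ape::node.depth.edgelength(tree)[path]
      lca <- path[which.min(depths)]
      d[i, j] <- d[j, i] <- sum(edge_len[setdiff(path, lca)])
    }
  }
  d
}

# independent connected-components oracle (plain union-find)
components_bruteforce <- function(dmat, threshold) {
  n <- nrow(dmat)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.finite(dmat[i, j]) && dmat[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# full-enumeration two-sample test oracle: exact permutation distribution
# of the Mann-Whitney U and Kolmogorov-Smirnov D statistics
perm_test_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  u_stat <- function(x, y) {
    sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  ks_stat <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(g) - ecdf(y)(g)))
  }
  u_obs <- u_stat(a, b)
  d_obs <- ks_stat(a, b)
  us <- apply(idx, 2, function(k) u_stat(pooled[k], pooled[-k]))
  ds <- apply(idx, 2, function(k) ks_stat(pooled[k], pooled[-k]))
  nu <- length(a) * length(b)
  list(
    mw_p = mean(pmin(us, nu - us) <= min(u_obs, nu - u_obs)),
    ks_p = mean(ds >= d_obs - 1e-12)
  )
}

# delimitation + metadata fixture where individuals link MOTUs into known
# merged groups: `groups` is a list of character vectors of motu ids that
# share individuals
linked_delim <- function(cluster_sizes, links) {
  motus <- paste0("m", seq_along(cluster_sizes))
  seqs <- unlist(lapply(seq_along(cluster_sizes), function(i) {
    paste0(motus[i], "_s", seq_len(cluster_sizes[i]))
  }))
  delim <- new_delimitation(
    tibble::tibble(seq_id = seqs, motu_id = sub("_s[0-9]+$", "", seqs)),
    provenance = "gmyc")
  ind <- setNames(paste0("ind_", delim$seq_id), delim$seq_id)
  # each link is a vector of motu ids; its first sequence in each motu is
  # assigned to one shared individual
  for (li in seq_along(links)) {
    for (mo in links[[li]]) {
      first_seq <- delim$seq_id[delim$motu_id == mo][1]
      ind[first_seq] <- paste0("shared", li)
    }
  }
  meta <- tibble::tibble(seq_id = delim$seq_id,
                         morphospecies = "Testospecies",
                         individual_id = unname(ind[delim$seq_id]),
                         clone_id = delim$seq_id,
                         type_label = NA_character_, year = 2010L)
  list(delim = delim, meta = meta)
}

default_bundle <- function(seed, ...) {
  emit_bundle(sim_config(seed = seed, ...))
}
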