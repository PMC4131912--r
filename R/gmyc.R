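#' Branching schedule of an ultrametric tree
#'
#' Computes node ages (tips at age zero) and the inter-event waiting
#' intervals that the mixed Yule-coalescent likelihood is evaluated over.
#' Polytomies are resolved arbitrarily with zero-length branches.
#'
#' @param tree An `ape::phylo` chronogram.
#' @param tol Relative ultrametricity tolerance (root-to-tip spread over
#'   tree height).
#' @return A `branching_schedule`: list with the (binary) tree, internal
#'   node `ages` sorted old to young, `height`, `n_tips`, and an
#'   `intervals` tibble (top/bottom age, duration, lineage count).
#' @export
branching_times <- function(tree, tol = 1e-6) {
  if (!tree_is_ultrametric(tree, tol)) {
    abort("tree is not ultrametric; supply a chronogram (time-calibrated tree)")
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  n <- length(tree$tip.label)
  ages_all <- node_ages(tree)
  ages_all[ages_all < 0] <- 0
  ages_all[seq_len(n)] <- 0  # tips exactly at the present
  ages <- sort(ages_all[(n + 1):(n + tree$Nnode)], decreasing = TRUE)
  bottoms <- c(ages[-1], 0)
  schedule <- list(
    tree = tree,
    ages = ages,
    ages_all = ages_all,
    height = ages[1],
    n_tips = n,
    intervals = tibble(age_top = ages, age_bottom = bottoms,
                       duration = ages - bottoms,
                       n_lineages = seq_along(ages) + 1L)
  )
  class(schedule) <- "branching_schedule"
  schedule
}

# Profile-likelihood of one branching block. `terms` holds, per interval,
# the positive rate bases (k for diversification, c*(c-1) per cluster for
# coalescence); the interval rate is lambda * sum(terms^p). lambda is
# profiled out in closed form; the block log-likelihood at the profiled
# lambda is returned.
block_loglik <- function(terms, durations, has_event, p) {
  s <- vapply(terms, function(v) if (length(v)) sum(v^p) else 0, 0)
  e <- sum(has_event)
  if (e == 0) return(0)
  exposure <- sum(s * durations)
  if (exposure <= 0) abort("degenerate schedule: zero exposure with events")
  e * log(e / exposure) + sum(log(s[has_event])) - e
}

# Maximize block_loglik over the scaling exponent p in [0, 2]; restarted
# over three subintervals to dodge local optima.
block_fit <- function(terms, durations, has_event, p = NULL) {
  if (sum(has_event) == 0) {
    return(list(logL = 0, lambda = 0, p = if (is.null(p)) 1 else p))
  }
  if (!is.null(p)) {
    p_hat <- p
  } else {
    cuts <- c(0, 2 / 3, 4 / 3, 2)
    best <- NULL
    for (j in 1:3) {
      o <- optimize(function(q) block_loglik(terms, durations, has_event, q),
                    lower = cuts[j], upper = cuts[j + 1],
                    maximum = TRUE, tol = 1e-8)
      if (is.null(best) || o$objective > best$objective) best <- o
    }
    p_hat <- best$maximum
  }
  s <- vapply(terms, function(v) if (length(v)) sum(v^p_hat) else 0, 0)
  lambda <- sum(has_event) / sum(s * durations)
  list(logL = block_loglik(terms, durations, has_event, p_hat),
       lambda = lambda, p = p_hat)
}

#' Null (single-process) branching log-likelihood
#'
#' One branching process over the whole tree: interval rate
#' `lambda * (n_i (n_i - 1))^p`. `lambda` is profiled in closed form; the
#' exponent `p` is optimized in `[0, 2]` unless fixed.
#'
#' @param schedule A [branching_times()] schedule.
#' @param p Optional fixed scaling exponent.
#' @return List with `logL`, `lambda` and `p`.
#' @export
null_loglik <- function(schedule, p = NULL) {
  iv <- schedule$intervals
  if (all(iv$duration == 0)) abort("degenerate schedule: all intervals have zero duration")
  k <- nrow(iv)
  # count lineages as 1 + nodes at or above the interval top, so exactly
  # tied node ages (zero-length intervals) are handled the same way as in
  # the mixed-model coalescent block; ties are compared with a relative
  # tolerance so uniform branch rescaling cannot flip them
  tol <- 1e-9 * schedule$height
  n_lin <- vapply(iv$age_top, function(a) 1 + sum(schedule$ages >= a - tol), 0)
  terms <- as.list(n_lin * (n_lin - 1))
  # coalescent bookkeeping: the event at the top of interval i is the
  # merge approached (backward in time) with interval i's lineage count;
  # the root event is conditioned on, so interval 1 carries no event
  has_event <- c(FALSE, rep(TRUE, k - 1))[seq_len(k)]
  block_fit(terms, iv$duration, has_event, p)
}

# Cluster structure of the tree cut at threshold age T: cluster roots are
# internal nodes at age <= T whose parent edge crosses T (or the root
# itself when T reaches the root age); tips whose parent is older than T
# are singletons.
clusters_at <- function(schedule, threshold) {
  tree <- schedule$tree
  n <- schedule$n_tips
  ages_all <- schedule$ages_all
  parent <- rep(NA_integer_, n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  internal <- (n + 1L):(n + tree$Nnode)
  is_root_cluster <- ages_all[internal] <= threshold &
    (internal == root | ages_all[parent[internal]] > threshold)
  cluster_roots <- internal[is_root_cluster]
  singletons <- which(seq_len(n) <= n & ages_all[parent[seq_len(n)]] > threshold)
  list(cluster_roots = cluster_roots, singleton_tips = singletons)
}

#' Mixed Yule-coalescent log-likelihood at a fixed threshold
#'
#' Events older than the threshold age `T` are diversification events with
#' interval rate `lambda_div * k^p_div` (`k` between-species lineages);
#' events younger than `T` are coalescences within the clusters obtained by
#' cutting the tree at `T`, with summed interval rate
#' `lambda_coal * sum_j (n_j (n_j - 1))^p_coal`. Both rates are profiled in
#' closed form; the exponents are optimized independently per block.
#'
#' @param schedule A [branching_times()] schedule.
#' @param threshold Threshold age in `(0, height]`.
#' @param p_div,p_coal Optional fixed scaling exponents.
#' @return List with `logL` and the four rate/exponent estimates.
#' @export
gmyc_loglik <- function(schedule, threshold, p_div = NULL, p_coal = NULL) {
  ages <- schedule$ages
  h <- schedule$height
  if (threshold <= 0 || threshold > h) {
    abort("threshold must lie in (0, tree height]")
  }
  bottoms <- c(ages[-1], 0)
  k <- length(ages)
  m <- sum(ages > threshold)

  # diversification block (forward-time Yule bookkeeping): intervals wholly
  # above T, each ending in the speciation event at its bottom with the
  # interval's lineage count, plus the event-free part of the straddling
  # interval above T
  div_terms <- list()
  div_dur <- numeric(0)
  div_event <- logical(0)
  if (m >= 1) {
    full <- seq_len(m - 1)
    div_terms <- as.list(full + 1)
    div_dur <- ages[full] - bottoms[full]
    div_event <- rep(TRUE, m - 1)
    div_terms <- c(div_terms, list(m + 1))
    div_dur <- c(div_dur, ages[m] - threshold)
    div_event <- c(div_event, FALSE)
  }

  # coalescent block (backward-time bookkeeping): intervals wholly below T;
  # the event at the top of interval i is the merge approached from the
  # present with interval i's per-cluster lineage counts. Between T and a
  # cluster root the cluster holds a single lineage (zero rate), so that
  # stretch carries neither exposure nor events. The root event, when it
  # falls below T (T at the tree height), is conditioned on.
  cl <- clusters_at(schedule, threshold)
  coal_idx <- if (m == 0) {
    seq_len(k)
  } else if (m + 1 <= k) {
    seq.int(m + 1, k)
  } else {
    integer(0)
  }
  desc_ages <- schedule$desc_ages
  coal_dur <- ages[coal_idx] - bottoms[coal_idx]
  coal_event <- ages[coal_idx] < threshold & coal_idx > 1
  cluster_age_sets <- lapply(cl$cluster_roots,
                             function(r) desc_ages[[as.character(r)]])
  coal_terms <- vector("list", length(coal_idx))
  tol <- 1e-9 * h
  for (j in seq_along(coal_idx)) {
    a_top <- ages[coal_idx[j]]
    cc <- vapply(cluster_age_sets, function(v) 1 + sum(v >= a_top - tol), 0)
    cc <- cc[cc >= 2]
    coal_terms[[j]] <- cc * (cc - 1)
  }

  div_fit <- block_fit(div_terms, div_dur, div_event, p_div)
  coal_fit <- block_fit(coal_terms, coal_dur, coal_event, p_coal)
  list(logL = div_fit$logL + coal_fit$logL,
       lambda_div = div_fit$lambda, p_div = div_fit$p,
       lambda_coal = coal_fit$lambda, p_coal = coal_fit$p,
       n_div_events = sum(div_event), n_coal_events = sum(coal_event))
}

# precompute, for every internal node, the ages of the internal nodes in
# its subtree (itself included); used to count lineages per cluster
precompute_desc_ages <- function(schedule) {
  tree <- schedule$tree
  n <- schedule$n_tips
  internal <- (n + 1L):(n + tree$Nnode)
  desc <- phangorn::Descendants(tree, internal, type = "all")
  out <- lapply(seq_along(internal), function(i) {
    nodes <- c(internal[i], desc[[i]][desc[[i]] > n])
    sort(schedule$ages_all[nodes])
  })
  names(out) <- as.character(internal)
  out
}

#' Fit the single-threshold GMYC model
#'
#' Evaluates the mixed Yule-coalescent likelihood at candidate thresholds
#' placed midway between consecutive distinct node ages (ages closer than
#' `1e-9` times the height are merged), plus the root age itself (which
#' reproduces the null single-process model exactly, so the maximized
#' likelihood can never fall below the null) and a candidate below the
#' youngest node (the all-singleton partition). The likelihood-ratio test
#' against the null uses a chi-square with `df` degrees of freedom
#' (default 3: five mixed-model parameters against two).
#'
#' @param tree Ultrametric `ape::phylo` tree with at least 3 tips.
#' @param df Degrees of freedom for the likelihood-ratio test (3 by
#'   convention; some authors use 2).
#' @param tol Ultrametricity tolerance passed to [branching_times()].
#' @return A `gmyc_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_single_threshold <- function(tree, df = 3, tol = 1e-6) {
  if (length(tree$tip.label) < 3) {
    abort("GMYC needs at least 3 tips; fit would be degenerate")
  }
  schedule <- branching_times(tree, tol)
  schedule$desc_ages <- precompute_desc_ages(schedule)
  h <- schedule$height

  distinct <- schedule$ages[c(TRUE, abs(diff(schedule$ages)) > 1e-9 * h)]
  mids <- if (length(distinct) > 1) {
    (distinct[-1] + distinct[-length(distinct)]) / 2
  } else {
    numeric(0)
  }
  candidates <- unique(c(h, mids, distinct[length(distinct)] / 2))

  fits <- lapply(candidates, function(tt) gmyc_loglik(schedule, tt))
  logls <- vapply(fits, `[[`, 0, "logL")
  best <- which.max(logls)
  opt <- fits[[best]]
  threshold <- candidates[best]

  null <- null_loglik(schedule)
  lr <- max(0, 2 * (logls[best] - null$logL))
  cl <- clusters_at(schedule, threshold)
  delim <- delimitation_from_clusters(schedule, cl)

  out <- list(
    threshold = threshold,
    lambda_div = opt$lambda_div, p_div = opt$p_div,
    lambda_coal = opt$lambda_coal, p_coal = opt$p_coal,
    logL_gmyc = logls[best], logL_null = null$logL,
    null_lambda = null$lambda, null_p = null$p,
    LR = lr, df = df,
    p_value = pchisq(lr, df = df, lower.tail = FALSE),
    clusters = length(cl$cluster_roots),
    entities = length(cl$cluster_roots) + length(cl$singleton_tips),
    delimitation = delim,
    n_tips = schedule$n_tips, height = h,
    event_ages = schedule$ages,
    candidates = tibble(threshold = candidates, logL = logls)
  )
  class(out) <- "gmyc_fit"
  out
}

delimitation_from_clusters <- function(schedule, cl) {
  tree <- schedule$tree
  n <- schedule$n_tips
  motu <- rep(NA_character_, n)
  for (i in seq_along(cl$cluster_roots)) {
    tips <- unlist(phangorn::Descendants(tree, cl$cluster_roots[i], "tips"))
    motu[tips] <- paste0("c", i)
  }
  for (j in seq_along(cl$singleton_tips)) {
    motu[cl$singleton_tips[j]] <- paste0("s", j)
  }
  d <- tibble(seq_id = tree$tip.label, motu_id = motu)
  d$motu_id <- as.character(match(d$motu_id, unique(d$motu_id)))
  new_delimitation(d, provenance = "gmyc")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("Single-threshold GMYC fit\n")
  cat(sprintf("  tips: %d  threshold age: %.6g (height %.6g)\n",
              x$n_tips, x$threshold, x$height))
  cat(sprintf("  logL (GMYC): %.4f  logL (null): %.4f\n",
              x$logL_gmyc, x$logL_null))
  cat(sprintf("  LR = %.4f, chi-square df = %d, p = %.4g\n",
              x$LR, x$df, x$p_value))
  cat(sprintf("  clusters: %d  entities: %d\n", x$clusters, x$entities))
  invisible(x)
}
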