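test_that("barcode gap detection finds the gap between tight clusters", {
  d <- block_matrix(c(5, 5), 0.002, 0.05)
  thr <- barcode_gap(d, prior = 0.01)
  expect_gt(thr, 0.002)
  expect_lt(thr, 0.05)

  # uniform continuum of ranked distances: no gap exceeds 1.5x the slope
  cont <- matrix(0, 10, 10)
  cont[upper.tri(cont)] <- seq(0.005, 0.1, length.out = 45)
  cont <- cont + t(cont)
  dimnames(cont) <- list(paste0("t", 1:10), paste0("t", 1:10))
  expect_true(is.na(barcode_gap(cont, prior = 0.01)))

  zero <- block_matrix(c(6), 0, 0)
  expect_true(is.na(barcode_gap(zero, prior = 0.01)))
})

test_that("threshold partitioning equals brute-force connected components", {
  d <- block_matrix(c(4, 3, 5), 0.003, 0.08)
  p <- partition_at(d, 0.02)
  expect_equal(motu_count(p), 3L)
  oracle <- components_bruteforce(d, 0.02)
  expect_equal(delimitation_ari(
    p, new_delimitation(tibble::tibble(seq_id = rownames(d),
                                       motu_id = as.character(oracle)))), 1)

  expect_equal(motu_count(partition_at(d, 0.001)), nrow(d))
  expect_equal(motu_count(partition_at(d, 1)), 1L)

  canonical <- function(x) match(x, unique(x))
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(runif(64), 8, 8)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(paste0("x", 1:8), paste0("x", 1:8))
    thr <- runif(1)
    expect_equal(canonical(partition_at(m, thr)$motu_id),
                 canonical(components_bruteforce(m, thr)))
  }
})

test_that("partitioning is monotone in the threshold", {
  set.seed(13)
  m <- matrix(runif(400, 0, 0.3), 20, 20)
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(paste0("x", 1:20), paste0("x", 1:20))
  counts <- vapply(seq(0.01, 0.3, by = 0.01),
                   function(t) motu_count(partition_at(m, t)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("recursive partitioning resolves the two-level fixture", {
  # cluster A tight at 0.001 (6 seqs), clusters B1/B2 tight at 0.001
  # separated by 0.04, A far from both at 0.3: the first ranked gap
  # (0.001 -> 0.04) yields a threshold near 0.02, which already isolates
  # A, B1 and B2; recursion finds nothing further to split
  n <- 12
  d <- matrix(0.3, n, n)
  d[1:6, 1:6] <- 0.001
  d[7:9, 7:9] <- 0.001
  d[10:12, 10:12] <- 0.001
  d[7:9, 10:12] <- 0.04
  d[10:12, 7:9] <- 0.04
  diag(d) <- 0
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  delim <- recursive_abgd(d, prior = 0.01)
  expect_equal(motu_count(delim), 3L)
  truth <- new_delimitation(tibble::tibble(
    seq_id = rownames(d), motu_id = rep(c("A", "B1", "B2"), c(6, 3, 3))))
  expect_equal(delimitation_ari(delim, truth), 1)

  # no gap anywhere: everything stays in one MOTU
  cont <- matrix(0, 10, 10)
  cont[upper.tri(cont)] <- seq(0.005, 0.1, length.out = 45)
  cont <- cont + t(cont)
  dimnames(cont) <- list(paste0("t", 1:10), paste0("t", 1:10))
  expect_equal(motu_count(recursive_abgd(cont, 0.01)), 1L)
})

test_that("recursion refines the top-level partition", {
  set.seed(41)
  for (i in 1:5) {
    b <- default_bundle(400 + i, clones_range = c(2, 4))
    d <- suppressWarnings(k80_matrix(b$alignment))
    prior <- 0.005
    thr <- barcode_gap(d, prior)
    if (is.na(thr)) next
    top <- partition_at(d, thr)
    rec <- recursive_abgd(d, prior)
    # every recursive MOTU is a subset of one top-level MOTU
    joined <- merge(rec, top, by = "seq_id")
    tab <- table(joined$motu_id.x, joined$motu_id.y)
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("prior scans produce plateaus and deterministic results", {
  d <- block_matrix(c(5, 5), 0.002, 0.5)
  series <- scan_priors(d)
  expect_equal(nrow(series$entries), 10L)
  expect_equal(series$plateaus$motu_count, 2L)
  expect_equal(series$plateaus$length, 10L)

  # identical inputs, identical outputs
  series2 <- scan_priors(d)
  expect_identical(series$entries$motu_count, series2$entries$motu_count)

  twin <- block_matrix(c(2), 0, 0)
  s3 <- scan_priors(twin)
  expect_true(all(s3$entries$motu_count == 1L))

  # two gap scales: small priors see 3 groups, larger priors only 2
  d2 <- matrix(0.5, 9, 9)
  d2[1:3, 1:3] <- 0.002
  d2[4:6, 4:6] <- 0.002
  d2[7:9, 7:9] <- 0.002
  d2[1:3, 4:6] <- d2[4:6, 1:3] <- 0.03
  diag(d2) <- 0
  dimnames(d2) <- list(paste0("t", 1:9), paste0("t", 1:9))
  s4 <- scan_priors(d2)
  expect_gte(nrow(s4$plateaus), 2L)
  expect_equal(max(s4$entries$motu_count), s4$entries$motu_count[1])
})

test_that("clone-splitting hypotheses are discarded before plateau choice", {
  # two true species; at small priors the intra-genomic structure of one
  # individual is split, which only the clone-consistency filter rejects
  labs <- c(paste0("a", 1:4), paste0("b", 1:4))
  d <- block_matrix(c(2, 2, 4), 0.0005, 0.2, labs)
  # a1,a2 and a3,a4 are clones of two individuals of species A, separated
  # by an intermediate distance that looks like a (false) barcode gap at
  # tiny priors
  d[1:2, 3:4] <- d[3:4, 1:2] <- 0.02
  meta <- tibble::tibble(
    seq_id = labs,
    individual_id = c("iA", "iA", "iA", "iA", "iB", "iB", "iC", "iC"))
  series <- scan_priors(d)
  sel <- select_delimitation(series, meta)
  expect_equal(motu_count(sel), 2L)
  expect_false(splits_individuals(sel, meta))
  expect_gt(nrow(attr(sel, "discarded")), 0L)

  # without clone information the finer split wins the first plateau
  sel_free <- select_delimitation(series)
  expect_gt(motu_count(sel_free), 2L)
})

test_that("selected delimitation matches truth on synthetic complexes", {
  ok <- 0
  for (i in 1:10) {
    b <- default_bundle(500 + i, clones_range = c(3, 3))
    dmat <- suppressWarnings(k80_matrix(b$alignment))
    sel <- abgd_delimit(dmat, b$meta)
    ok <- ok + (delimitation_ari(sel, b$truth) == 1)
  }
  expect_gte(ok, 9)
})

test_that("a gapless complex with high intra-genomic diversity is lumped", {
  # continuum of divergence where clone pairs of one individual span the
  # whole range: every split separates clones, so only the single-MOTU
  # hypothesis survives the clone-consistency filter
  set.seed(77)
  n <- 14
  pos <- cumsum(runif(n, 0.004, 0.008))
  d <- abs(outer(pos, pos, "-"))
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  meta <- tibble::tibble(seq_id = paste0("t", 1:n),
                         individual_id = paste0("i", rep(1:7, 2)))
  sel <- abgd_delimit(d, meta)
  expect_equal(motu_count(sel), 1L)
  expect_false(splits_individuals(sel, meta))
})
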