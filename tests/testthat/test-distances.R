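test_that("K80 distances match the closed form on counted substitutions", {
  # 100 transitions and 50 transversions over 1000 sites
  aln <- counted_pair_aln(1000, 100, 50)
  d <- k80_matrix(aln)
  expect_equal(d["s1", "s2"], k80_closed_form(0.1, 0.05), tolerance = 1e-6)
  expect_equal(d["s1", "s2"], 0.1701797, tolerance = 1e-5)

  same <- tiny_aln(x = "ACGTACGT", y = "ACGTACGT")
  expect_equal(k80_matrix(same)["x", "y"], 0)

  gapped <- tiny_aln(x = "ACGT----", y = "----ACGT", z = "ACGTACGT")
  expect_error(k80_matrix(gapped), "no comparable sites")
})

test_that("K80 never falls below the p-distance", {
  set.seed(5)
  for (i in 1:20) {
    n <- 400
    x <- sample(c("A", "C", "G", "T"), n, TRUE)
    y <- x
    mut <- sample.int(n, sample(5:60, 1))
    y[mut] <- vapply(y[mut], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    aln <- tiny_aln(a = paste(x, collapse = ""), b = paste(y, collapse = ""))
    p <- mean(x != y)
    expect_gte(k80_matrix(aln)["a", "b"] + 1e-12, p)
  }
})

test_that("patristic distances equal brute-force path sums", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
  expect_equal(patristic_matrix(tr)["A", "B"], 0.3)

  set.seed(21)
  for (i in 1:20) {
    tree <- ape::rtree(sample(4:32, 1))
    expect_equal(patristic_matrix(tree), patristic_bruteforce(tree),
                 tolerance = 1e-12)
  }

  chrono <- ape::rcoal(8)
  pm <- patristic_matrix(chrono)
  # pairs whose path crosses the root of an ultrametric tree are all at
  # twice the tree height
  kids <- phangorn::Descendants(chrono, phangorn::Children(chrono, 9), "tips")
  height <- max(ape::node.depth.edgelength(chrono)[1:8])
  cross <- pm[kids[[1]], kids[[2]]]
  expect_equal(unname(as.vector(cross)), rep(2 * height, length(cross)),
               tolerance = 1e-9)
  expect_equal(unname(diag(pm)), rep(0, 8))

  neg <- ape::read.tree(text = "((A:0.1,B:-0.05):0.1,C:0.2);")
  expect_warning(pmn <- patristic_matrix(neg), "clamped")
  expect_gte(min(pmn), 0)
})

test_that("distance classes carry combinatorial pair counts", {
  # 2 types (3 + 4 sequences), one individual with 2 clones inside type 1
  labs <- c(paste0("a", 1:3), paste0("b", 1:4))
  d <- block_matrix(c(3, 4), 0.01, 0.1, labs)
  meta <- tibble::tibble(
    seq_id = labs,
    individual_id = c("iA", "iA", "iB", "iC", "iD", "iE", "iF"))
  delim <- new_delimitation(
    tibble::tibble(seq_id = labs, motu_id = rep(c("T1", "T2"), c(3, 4))))
  cls <- classify_distances(d, meta, delim)
  s <- tidy(cls)
  expect_equal(s$n[s$class == "inter_type"], 3L * 4L)
  expect_equal(s$n[s$class == "intra_genomic"], 1L)
  expect_equal(s$n[s$class == "intra_type"], 3L + 6L - 1L)
  expect_equal(s$n[s$class == "overall"], choose(7, 2))
  expect_equal(s$median_pct[s$class == "inter_type"], 10)

  # single MOTU, no clones: no inter pairs, overall equals intra_type
  meta1 <- tibble::tibble(seq_id = labs, individual_id = paste0("i", 1:7))
  delim1 <- new_delimitation(tibble::tibble(seq_id = labs, motu_id = "T1"))
  cls1 <- classify_distances(d, meta1, delim1)
  expect_equal(tidy(cls1)$n[tidy(cls1)$class == "inter_type"], 0L)
  expect_equal(sort(class_values(cls1, "intra_type")),
               sort(class_values(cls1, "overall")))
})

test_that("gap statistics report separation and overlap", {
  mk <- function(intra, inter) {
    v <- tibble::tibble(class = rep(c("intra_type", "inter_type"),
                                    c(length(intra), length(inter))),
                        distance = c(intra, inter))
    structure(list(values = v, summary = NULL), class = "distance_classes")
  }
  g <- gap_statistics(mk(0.01, 0.05))
  expect_equal(g$gap_pct, 4)
  expect_false(g$overlap)

  g2 <- gap_statistics(mk(c(0.01, 0.03), c(0.02, 0.05)))
  expect_true(g2$overlap)

  g3 <- gap_statistics(mk(numeric(0), 0.05))
  expect_false(g3$defined)
  expect_true(is.na(g3$gap))

  b <- default_bundle(301, clones_range = c(3, 3))
  cls <- classify_distances(suppressWarnings(k80_matrix(b$alignment)),
                            b$meta, b$truth)
  expect_false(gap_statistics(cls)$overlap)
})

test_that("distribution tests agree with a full-enumeration oracle", {
  expect_false(compare_distributions(c(1, 2), c(1, 2, 3))$conclusive)

  a <- c(1, 2, 3, 4, 5, 6) / 10
  b <- a + 2  # disjoint supports
  r <- compare_distributions(a, b)
  expect_equal(r$mw_u, 0)
  expect_lt(r$ks_p, 0.01)

  same <- compare_distributions(a, a)
  expect_gt(same$mw_p, 0.9)
  expect_gt(same$ks_p, 0.9)

  set.seed(9)
  x <- round(rnorm(6), 2)
  y <- round(rnorm(7, mean = 0.8), 2)
  r2 <- compare_distributions(x, y)
  oracle <- perm_test_oracle(x, y)
  expect_equal(r2$mw_p, oracle$mw_p, tolerance = 0.01)
  expect_equal(r2$ks_p, oracle$ks_p, tolerance = 0.05)
})

test_that("NJ solves the 3-taxon case exactly and recovers 4-taxon splits", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.3
  d["A", "C"] <- d["C", "A"] <- 0.5
  d["B", "C"] <- d["C", "B"] <- 0.6
  tr <- nj_tree(d)
  pm <- patristic_matrix(tr)
  expect_equal(pm[rownames(d), colnames(d)], d, tolerance = 1e-12)

  # additive 4-taxon matrix with split AB|CD
  tr4 <- ape::read.tree(text = "((A:0.05,B:0.07):0.2,(C:0.06,D:0.04):0.15);")
  d4 <- patristic_matrix(tr4)
  rebuilt <- nj_tree(d4)
  expect_equal(patristic_matrix(rebuilt)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-12)

  two <- nj_tree(d[1:2, 1:2])
  expect_equal(patristic_matrix(two)["A", "B"], 0.3)
})

test_that("UPGMA reproduces ultrametric input distances", {
  chrono <- ape::rcoal(10)
  d <- patristic_matrix(chrono)
  rebuilt <- upgma_chronogram(d)
  expect_equal(patristic_matrix(rebuilt)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  depths <- ape::node.depth.edgelength(rebuilt)[1:10]
  expect_lt(max(depths) - min(depths), 1e-12)
})

test_that("PHYLIP square matrices round-trip", {
  d <- block_matrix(c(2, 3), 0.012345678, 0.23456789)
  path <- withr::local_tempfile(fileext = ".phy")
  write_phylip(d, path)
  back <- read_phylip(path)
  expect_equal(back, d, tolerance = 1e-7)
})
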