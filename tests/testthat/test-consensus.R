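test_that("clone-sharing MOTUs merge to the known worked examples", {
  # seven clusters linked by shared individuals into four putative species
  fx <- linked_delim(rep(2, 7), links = list(c("m1", "m2"), c("m3", "m4"),
                                             c("m5", "m6")))
  merged <- merge_clone_splits(fx$delim, fx$meta)
  expect_equal(motu_count(fx$delim), 7L)
  expect_equal(motu_count(merged), 4L)

  # five clusters plus four singletons collapsing into two putative species
  fx2 <- linked_delim(c(3, 3, 3, 3, 3, 1, 1, 1, 1),
                      links = list(c("m1", "m2", "m6", "m7"),
                                   c("m3", "m4", "m5", "m8", "m9")))
  expect_equal(motu_count(fx2$delim), 9L)
  merged2 <- merge_clone_splits(fx2$delim, fx2$meta)
  expect_equal(motu_count(merged2), 2L)
  expect_false(splits_individuals(merged2, fx2$meta))
})

test_that("merging is idempotent, only coarsens, and respects individuals", {
  set.seed(51)
  for (i in 1:5) {
    n_cl <- sample(4:9, 1)
    links <- list(sample(paste0("m", 1:n_cl), 2))
    fx <- linked_delim(rep(2, n_cl), links)
    m1 <- merge_clone_splits(fx$delim, fx$meta)
    m2 <- merge_clone_splits(m1, fx$meta)
    expect_equal(m1$motu_id, m2$motu_id)
    expect_lte(motu_count(m1), motu_count(fx$delim))
    # coarsening: members of one original MOTU never end up separated
    joined <- merge(fx$delim, m1, by = "seq_id")
    expect_true(all(tapply(joined$motu_id.y, joined$motu_id.x,
                           function(x) length(unique(x))) == 1))
    expect_false(splits_individuals(m1, fx$meta))
  }

  # no shared individuals: identity
  fx0 <- linked_delim(rep(2, 3), links = list())
  m0 <- merge_clone_splits(fx0$delim, fx0$meta)
  expect_equal(motu_count(m0), 3L)
  expect_equal(delimitation_ari(m0, fx0$delim), 1)
})

test_that("singleton screening flags short and old sequences", {
  base <- strrep("ACGTG", 140)  # 700 bp
  seqs <- setNames(rep(base, 5), paste0("g", 1:5))
  seqs["g5"] <- paste0(strrep("-", 300), substr(base, 301, 700))  # 400 bp
  aln <- tiny_aln(seqs)
  meta <- tibble::tibble(seq_id = names(seqs), year = rep(2010L, 5))
  delim <- new_delimitation(tibble::tibble(
    seq_id = names(seqs), motu_id = c("A", "A", "A", "A", "S1")))

  flags <- screen_singletons(delim, meta, aln)$flags
  expect_equal(flags$seq_id, "g5")
  expect_true(grepl("short", flags$reasons))

  meta$year[meta$seq_id == "g5"] <- 1996L
  out2 <- screen_singletons(delim, meta, aln)
  expect_true(grepl("old", out2$flags$reasons))

  applied <- screen_singletons(delim, meta, aln, apply_screen = TRUE)
  expect_equal(motu_count(applied$delimitation), 1L)
})

test_that("singleton screening flags planted 5'-concentrated errors", {
  base <- strrep("ACGTG", 140)
  planted <- c(3, 9, 20, 41, 77, 120, 150)
  noisy <- strsplit(base, "")[[1]]
  noisy[planted] <- ifelse(noisy[planted] == "T", "A", "T")
  aln <- tiny_aln(a1 = base, a2 = base, a3 = base,
                  s = paste(noisy, collapse = ""))
  meta <- tibble::tibble(seq_id = aln$seq_id, year = 2010L)
  delim <- new_delimitation(tibble::tibble(seq_id = aln$seq_id,
                                           motu_id = c("A", "A", "A", "S")))
  flags <- screen_singletons(delim, meta, aln)$flags
  expect_true(flags$suspect[flags$seq_id == "s"])
  expect_true(grepl("five_prime", flags$reasons[flags$seq_id == "s"]))
  # mismatch-position oracle: every planted difference sits in the first
  # quarter of the 700 columns
  expect_true(all(planted <= 175))
})

test_that("a full-length singleton with spread-out differences passes", {
  base <- strrep("ACGTG", 140)
  spread <- strsplit(base, "")[[1]]
  spread[seq(10, 690, by = 100)] <- "T"
  aln <- tiny_aln(a1 = base, a2 = base, a3 = base, s = paste(spread, collapse = ""))
  meta <- tibble::tibble(seq_id = aln$seq_id, year = 2010L)
  delim <- new_delimitation(tibble::tibble(seq_id = aln$seq_id,
                                           motu_id = c("A", "A", "A", "S")))
  flags <- screen_singletons(delim, meta, aln)$flags
  expect_false(flags$suspect[flags$seq_id == "s"])
})

test_that("cross-validation issues the four verdicts in precedence order", {
  labs <- c(paste0("a", 1:4), paste0("b", 1:4), paste0("c", 1:4))
  meta <- tibble::tibble(
    seq_id = labs,
    individual_id = rep(c("i1", "i1", "i2", "i3", "i4", "i4", "i5", "i6",
                          "i7", "i7", "i8", "i9"), length.out = 12))
  delim <- new_delimitation(tibble::tibble(
    seq_id = labs, motu_id = rep(c("T1", "T2", "T3"), each = 4)))

  # well-separated types: validated
  d_ok <- block_matrix(c(4, 4, 4), 0.005, 0.15, labs)
  v1 <- crossvalidate(delim, d_ok, meta)
  expect_equal(v1$verdict, "validated")
  expect_false(v1$gap$overlap)

  # inter medians inside the intra-genomic range: invalid_low_inter
  d_low <- block_matrix(c(4, 4, 4), 0.006, 0.005, labs)
  expect_equal(crossvalidate(delim, d_low, meta)$verdict, "invalid_low_inter")

  # overlapping intra and inter distances: invalid_overlap
  d_over <- block_matrix(c(4, 4, 4), 0.05, 0.06, labs)
  diag(d_over) <- 0
  d_over["a1", "a2"] <- d_over["a2", "a1"] <- 0.08  # intra above min inter
  # keep the clone pair low so the intra-genomic ceiling stays below inter
  d_over["a1", "a2"] <- d_over["a2", "a1"] <- 0.08
  meta2 <- meta
  meta2$individual_id <- paste0("u", 1:12)  # no clones: skip low-inter rule
  expect_equal(crossvalidate(delim, d_over, meta2)$verdict, "invalid_overlap")

  # single type: no inter distances, inconclusive
  one <- new_delimitation(tibble::tibble(seq_id = labs, motu_id = "T1"))
  expect_equal(crossvalidate(one, d_ok, meta)$verdict, "inconclusive")
})

test_that("congruence counts identical MOTUs and the adjusted Rand index", {
  a <- new_delimitation(tibble::tibble(seq_id = paste0("s", 1:9),
                                       motu_id = rep(c("x", "y", "z"), each = 3)))
  expect_equal(congruence(a, a)$fraction, 1)
  expect_equal(congruence(a, a)$ari, 1)
  expect_equal(congruence(a, a)$identical_motus, 3L)

  # a splits one of b MOTUs in two
  b <- a
  split_a <- a
  split_a$motu_id[split_a$seq_id == "s1"] <- "x2"
  r <- congruence(split_a, b)
  expect_equal(r$identical_motus, motu_count(b) - 1L)
  expect_lt(r$ari, 1)

  singletons <- new_delimitation(tibble::tibble(seq_id = paste0("s", 1:9),
                                                motu_id = as.character(1:9)))
  lumped <- new_delimitation(tibble::tibble(seq_id = paste0("s", 1:9),
                                            motu_id = "all"))
  expect_equal(congruence(singletons, lumped)$fraction, 0)

  disjoint <- new_delimitation(tibble::tibble(seq_id = paste0("t", 1:3),
                                              motu_id = "m"))
  expect_error(congruence(a, disjoint), "disjoint")
})

test_that("the species table marks congruent, conflicting and ambiguous rows", {
  labs <- paste0("s", 1:9)
  meta <- tibble::tibble(seq_id = labs, morphospecies = "Testospecies")
  truthy <- new_delimitation(tibble::tibble(
    seq_id = labs, motu_id = rep(c("1", "2", "3"), each = 3)))
  ok <- list(abgd = list(verdict = "validated"),
             gmyc = list(verdict = "validated"))

  tab <- build_species_table(NULL, truthy, truthy, ok, meta)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$status == "congruent-species"))
  expect_true(all(tab$gmyc_match))

  other <- truthy
  other$motu_id[other$seq_id == "s1"] <- "2"
  tab2 <- build_species_table(NULL, truthy, other, ok, meta)
  expect_true(any(tab2$status == "method-conflict"))

  amb <- list(abgd = list(verdict = "inconclusive"),
              gmyc = list(verdict = "validated"))
  tab3 <- build_species_table(NULL, truthy, truthy, amb, meta)
  expect_true(all(tab3$status == "ambiguous"))
})
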