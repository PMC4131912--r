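Package: foramdelim
Title: Molecular Species Delimitation for Planktonic Foraminifera
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delimits (pseudo)cryptic species from partial SSU rDNA sequence
    data using three complementary lines of evidence: distance-based barcode
    gap partitioning over Kimura two-parameter distances, single-threshold
    general mixed Yule-coalescent (GMYC) fitting on ultrametric trees, and
    cross-validation of candidate partitions against patristic distance
    distributions, including intra-genomic (clone-to-clone) baselines. Adds
    the bookkeeping that multi-copy rDNA requires: dereplication of identical
    sequences over a homologous block, clone-consistency filtering and
    merging, screening of short or degraded singleton sequences, and a
    consensus species table comparing methods. Ships a seeded synthetic-data
    generator emulating barcode-gapped species complexes with coalescent
    within-species variation, non-concerted intra-genomic rDNA copy
    variation, heterogeneous lineage rates, and degraded sequences, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    mclust,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
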