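# foramdelim

Molecular delimitation of (pseudo)cryptic species in planktonic
foraminifera from partial SSU rDNA sequences.

Most modern planktonic foraminiferal morpho-species turn out to be
complexes of divergent SSU rDNA lineages ("genetic types"), but those
types have historically been delimited by eye, one publication at a time.
`foramdelim` is for micropaleontologists and protist molecular ecologists
who want those delimitations made reproducible: it implements two
independent automatic methods and the distance-based cross-checks needed
to decide which genetic types deserve species status, together with the
bookkeeping that multi-copy rDNA imposes (clones of one individual must
never end up in different species).

## What it computes

**Barcode-gap partitioning (ABGD-style).** Pairwise Kimura two-parameter
distances, d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q) with transition/
transversion proportions P and Q over pairwise-complete sites, are ranked
and scanned for the first gap above a prior intraspecific ceiling *P*
whose width exceeds *X* = 1.5 times the local slope of the ranked
distances. Sequences are partitioned as connected components below the
gap's midpoint, recursively, over 10 log-spaced priors in [0.001, 0.1];
clone-splitting hypotheses are discarded and the first MOTU-count plateau
(maximum count) is selected.

**Single-threshold GMYC.** On an ultrametric tree, a threshold age *T*
separates diversification branching (rate λ_div·k^p_div over k lineages)
from within-cluster coalescence (rate λ_coal·Σ_j n_j(n_j−1)^p_coal).
The likelihood Π_i b_i·e^(−b_i·x_i) over inter-event intervals is profiled
over both rates, the exponents optimized in [0, 2], *T* chosen over
candidates between consecutive node ages, and a likelihood-ratio test
(χ², df = 3) compares against the single-process null.

**Patristic cross-validation.** Tip-to-tip path lengths are classified
into inter-type, intra-type and intra-genomic (clone-to-clone) distances;
a candidate delimitation is *validated* when inter-type distances sit
above the intraspecific range with a positive barcode gap, and
invalidated when they overlap intra-type distances or sink into the
intra-genomic range (Kolmogorov–Smirnov and Mann–Whitney tests attached).

**Consensus.** Clone-split MOTUs are merged, artifact singletons (short,
old, or 5′-degraded sequences) are flagged, method congruence is scored
(identical MOTUs, fraction, adjusted Rand index) and a species table
labels every candidate species congruent / conflicting / ambiguous.

A seeded synthetic generator (`sim_config()`, `emit_bundle()`) produces
species complexes with a controlled barcode gap, coalescent within-species
variation, intra-genomic copy variation, heterogeneous lineage rates and
degraded sequences, with truth labels, so the whole pipeline is testable
without downloads.

## Worked example

```r
library(foramdelim)

cfg    <- sim_config(seed = 42, clones_range = c(3, 3))  # 5 species, 75 seqs
bundle <- emit_bundle(cfg)

dmat <- k80_matrix(bundle$alignment)
abgd <- abgd_delimit(dmat, bundle$meta)
abgd
#> Delimitation (abgd): 5 MOTUs over 75 sequences

fit <- fit_single_threshold(bundle$chronogram)
fit
#> Single-threshold GMYC fit
#>   tips: 75  threshold age: 0.0275 (height 0.15)
#>   logL (GMYC): 629.1331  logL (null): 616.1094
#>   LR = 26.0473, chi-square df = 3, p = 9.322e-06
#>   clusters: 5  entities: 5

congruence(abgd, merge_clone_splits(fit$delimitation, bundle$meta))
#> # A tibble: 1 × 6
#>   identical_motus motus_a motus_b fraction   ari n_shared
#>             <int>   <int>   <int>    <dbl> <dbl>    <int>
#> 1               5       5       5        1     1       75

tidy(classify_distances(dmat, bundle$meta, abgd))[, c("class", "n", "median_pct")]
#> # A tibble: 4 × 3
#>   class             n median_pct
#>   <chr>         <int>      <dbl>
#> 1 inter_type     2250     25.0
#> 2 intra_type      450      0.718
#> 3 intra_genomic    75      0.286
#> 4 overall        2775     20.7
```

Both methods independently recover the five simulated species
(`fraction = 1`, `ari = 1`); the GMYC threshold (0.0275) falls between
the within-species coalescent depths and the species divergences, and the
distance classes show the validated-species signature — intra-genomic
(0.29%) below intra-type (0.72%) far below inter-type (25%) divergence,
with no overlap (`gap_statistics()` reports a 7.9-point gap).

`run_all(run_config(sim = cfg))` chains every stage (distances → ABGD →
GMYC → consensus) and returns the per-species evidence, the congruence
report and the species table; `autoplot()` methods draw the distance-class
boxplots and the lineage-through-time plot with the fitted threshold.

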