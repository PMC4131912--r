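---
title: "Delimiting cryptic species from SSU rDNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting cryptic species from SSU rDNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foramdelim)
```

## The problem

Planktonic foraminiferal morpho-species — taxa defined on shell
morphology — commonly hide several divergent SSU rDNA lineages. Whether
such a lineage ("genetic type") is a genuine cryptic species cannot be
settled by eyeballing a tree: sequence sets are heterogeneous in length
and quality, substitution rates vary enormously among lineages, and the
marker is multi-copy, so two sequences from one individual (clones of one
PCR product pool) need not be identical. `foramdelim` combines three
lines of evidence that fail in different ways: a distance-based barcode
gap criterion, a branching-rate (mixed Yule–coalescent) criterion on a
time tree, and distributional cross-checks of any candidate partition
against the within-individual (intra-genomic) baseline.

This vignette records the models, the tunable parameters and the design
choices that were genuinely open, so results can be interpreted — and
challenged — precisely.

## Distances

K80 distances are computed with pairwise deletion: for each pair,
transition and transversion proportions are counted over sites where both
sequences carry an unambiguous base, and
`d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Pairwise deletion is the
only defensible option for archival rDNA data, where sequences overlap
irregularly; complete-case deletion would discard most sites. Pairs whose
log argument is non-positive are *saturated*: they are set to `Inf`,
flagged, and excluded from summaries with a warning — at SSU inter-type
divergences of tens of percent this is a real possibility, and silently
truncating such distances would bias the gap statistics.

Patristic distances are tip-to-tip path sums on a user-supplied
phylogram. They are preferred over raw pairwise distances because the
tree-based estimate accounts for multiple substitutions along the path.
Negative branch lengths (possible in distance-based trees) are clamped to
zero with a warning. Distances are reported in outputs as percent
nucleotide change (distance × 100).

Distance classes are disjoint sets of unordered pairs: `intra_genomic`
(same individual), `intra_type` (same MOTU, different individuals),
`inter_type` (different MOTUs), plus `overall`. The class summaries carry
median, quartiles and Tukey bounds (Q1 − 1.5·IQR, Q3 + 1.5·IQR). The gap
statistic is `min(inter) − max(intra)` with the intra side pooling
intra-type and intra-genomic pairs — clones are intraspecific
observations and belong under the intraspecific ceiling. Distribution
comparisons use two-sided Kolmogorov–Smirnov and Mann–Whitney tests (the
latter exact when both samples have ≤ 8 values); classes below 3 values
return an inconclusive report instead of a p-value, because a "test" on
two distances is noise dressed up as inference.

## Barcode-gap partitioning

Given a prior maximum intraspecific divergence `P`, the ranked pairwise
distances are scanned for the first gap that (i) ends above `P`,
(ii) is wider than `X = 1.5` times the local slope, estimated as the mean
of the preceding `slope_window = 10` ranked increments, and (iii) is at
least as wide as `P` itself — a species-level discontinuity cannot be
narrower than the divergence one is willing to call intraspecific. The
gap's midpoint becomes a threshold; MOTUs are connected components of the graph
linking pairs closer than the threshold, so chains of small distances
keep populations together. The procedure recurses inside every MOTU of at
least three sequences (gap detection is undefined below that) until no
qualifying gap remains. Two boundary rules matter and are deliberate:

* at the very first rank there are no preceding increments, so the slope
  is taken from the *following* window — otherwise any smooth continuum
  would be split at its start;
* a detected gap whose threshold still leaves a single connected
  component (pure chaining) ends the recursion for that group, since no
  refinement is possible.

The prior is scanned over 10 log-spaced values in [0.001, 0.1] (the
original ABGD software's defaults; configurable via `abgd_config()`). Contiguous runs
of equal MOTU count form plateaus. Selection follows the field's
workflow: hypotheses that place clones of one individual in different
MOTUs are discarded outright; among the survivors a plateau is eligible
when it spans more than a factor of two in prior — the prior is only an
order-of-magnitude guess, so a partition worth calling species-level
should survive a doubling of it (narrower runs, and finally single
points, are used only when nothing else exists) — and the eligible
plateau with the maximum MOTU count wins, ties broken toward the smaller
prior.

Both the prior-width floor and the factor-of-two plateau span exist to
keep a specific artifact out: a deep within-species coalescence in a
fast-evolving lineage can mimic a narrow, clone-consistent barcode gap
over a sliver of the prior range. On the synthetic benchmark the
selection recovers the true partition in 97–100 of 100 complexes; on
real material, anything that still slips through is what the patristic
cross-validation exists to catch.

## Single-threshold GMYC

On an ultrametric tree with node ages `a_1 > a_2 > ...` (tips at age 0),
a threshold age `T` classifies branching events: older events are
speciations, younger events are coalescences inside the clusters obtained
by cutting the tree at `T`. Each inter-event interval `i` contributes
`b_i exp(-b_i x_i)`; intervals above `T` carry the diversification rate
`lambda_div * k^p_div` (k lineages present), intervals below `T` the
summed coalescent rate `lambda_coal * sum_j (n_j (n_j - 1))^p_coal`.
Exactly one process is active per interval, which is what makes both
rates profileable in closed form (`lambda_hat = events / exposure`); the
scaling exponents are optimized by bounded scalar search on [0, 2]
(tolerance 1e-8, restarted on three subintervals).

Event bookkeeping follows each process's natural direction: a speciation
event ends its interval forward in time and is charged the interval's
lineage count; a coalescence is approached backward from the present and
is charged the lineage count of the interval *below* it (so a cluster's
root event carries rate `2·1`, never zero). The root event is conditioned
on throughout.

Candidate thresholds sit midway between consecutive distinct node ages
(ages closer than 1e-9 of the height are merged), plus a candidate below
the youngest node (the all-singleton cut) and the root age itself. At the
root-age candidate the mixed model reproduces the null single-process
model exactly, which guarantees `logL_GMYC >= logL_null` at the optimum
by construction rather than by optimizer luck. Lineage counts compare
ages with a relative tolerance of 1e-9·height so that exactly tied node
ages (which the synthetic generator produces by design) are handled
identically in the null and mixed models, and uniform rescaling of branch
lengths cannot flip a tie — the delimitation is scale-invariant.

The likelihood-ratio test uses a chi-square with `df = 3` (five mixed
parameters against two), the convention of the original GMYC software;
the literature also uses 2, so it is an argument. On 100 single-population
coalescent trees of 30 tips the df = 3 test rejects at the 5% level about
1–5 times — conservative, as expected when the threshold parameter is
only identified under the alternative.

Two behavioral notes. First, under profile likelihood the youngest cherry
of a tree is almost always worth claiming as a two-tip cluster, so the
fitted optimum essentially never returns an all-singleton partition on
generic trees; the all-singleton delimitation exists as the low-threshold
cut and is tested at that level. Second, polytomies are resolved
arbitrarily with zero-length branches before fitting.

## Clone consistency, screening, verdicts

`merge_clone_splits()` unions MOTUs sharing an individual until a
fixpoint; it only coarsens, is idempotent, and the pipeline asserts
afterwards that no individual spans two MOTUs. `screen_singletons()`
flags singleton MOTUs that look like sequencing artifacts: shorter than
500 bp, submitted before 2000, or with more than half of their mismatches
against the nearest MOTU's majority consensus inside the first quarter of
the alignment (the 5′-degradation signature; at least 4 mismatches are
required before the positional rule fires). Flags are advisory by default
— the screen mimics a judgment call, not a law — and merging is opt-in.

`crossvalidate()` recomputes the distance classes under a candidate
delimitation and issues a verdict in fixed precedence:
`inconclusive` (inter- or intraspecific class below 3 pairs), then
`invalid_low_inter` (median inter-type distance at or below the
intra-genomic maximum — "species" whose separation is indistinguishable
from rDNA copy variation), then `invalid_overlap`
(`min(inter) < max(intra)`), else `validated`. `congruence()` counts
MOTUs with exactly identical member sets (restricted to the shared
sequences, which is reported), the fraction relative to the first
argument's MOTU count, and the adjusted Rand index.
`build_species_table()` marks a candidate species `congruent-species`
only when both methods delimit the identical sequence set *and* the
verdicts validate it.

## The synthetic generator

`sim_config()` describes the data-generating process the analysis
assumes, with truth labels:

| parameter | default | meaning |
|---|---|---|
| `k_species` | 5 | species separated by a barcode gap |
| `n_individuals` | 5 | individuals per species (Kingman coalescent) |
| `clones_range` | 2–7 | rDNA clones sequenced per individual |
| `coal_depth` | 0.01 subst/site | max within-species tip divergence |
| `intragenomic_div` | 0.003 | clone-to-clone divergence within one individual |
| `gap_factor` | 10 | smallest between-species divergence / `coal_depth` |
| `root_spread` | 3 | deepest / shallowest species divergence |
| `rate_sdlog` | 0.25 | log-normal sd of per-species rate multipliers |
| `kappa` | 2 | K80 transition/transversion ratio |
| `seq_length` | 700 bp | homologous-block scale |

The within-species values sit inside the observed ranges for the group
(intra-type medians of a fraction of a percent to ~3%, intra-genomic
medians 0.25–2.6%); the rate heterogeneity is a bounded nod to the
enormous inter-lineage rate spread in this group — the full spread would
saturate K80 at 700 bp and test the saturation handling rather than the
delimitation. Species node ages are remapped linearly onto
[gap·coal/2, root_spread·gap·coal/2], individual coalescents onto
[max(1.5·h_clone, 0.1·h_within), coal_depth/2], and clone trees scaled to
intragenomic_div/2, giving an exactly ultrametric chronogram with species
monophyletic by construction. Sequences evolve under continuous-time K80
(`phangorn::simSeq`) along a phylogram whose species clades (stem
included) carry the rate multipliers; the chronogram keeps clock time, so
rate heterogeneity decouples the two inputs just as real
phylogram/chronogram pairs do. Degradation truncates a configured
fraction of sequences from the 5′ end and plants extra substitutions in
the first quarter of columns, back-dating those records to 1996.

What the generator does *not* emulate — and therefore what passing tests
cannot certify on real data: indels and alignment uncertainty (the
alignment is identity by construction; gaps arise only from truncation),
rRNA secondary structure and expansion segments, PCR chimeras,
tree-estimation error (the chronogram handed to GMYC is the true one;
real chronograms are estimates with their own uncertainty), and
taxonomic misassignment in public databases.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 100 random trees of up to
32 tips for the exact patristic oracle; 100 bundles of 75 sequences
(5 species × 5 individuals × 3 clones, gap factor 10) for delimitation
recovery; 100 coalescent trees of 30 tips for LRT calibration; 10–20
default bundles for the distance-class ordering — sizes chosen so the
whole suite runs in a few minutes on one core while keeping binomial
noise on the stochastic checks well inside their margins.

Tolerances worth knowing: ultrametricity is accepted when the
root-to-tip spread is ≤ 1e-6 of the height; node-age ties merge at
1e-9·height; exponent optimization stops at 1e-8; saturated K80 pairs
are excluded from summaries; NJ's negative branch lengths clamp to zero;
dereplication compares uppercased sequences literally (ambiguity codes
are not expanded), keeps the first-seen representative, and downstream
partitions are re-expanded to all members before any clone logic runs.

## Known limitations

* ABGD's first-plateau rule can select a clone-consistent over-split in
  a few percent of well-behaved complexes (see above); on real data the
  cross-validation verdicts are the guard.
* The GMYC fit prefers clustering recent cherries; isolated deep tips
  are delimited as singletons only via the threshold geometry, and
  artifact singletons must be caught by the screening rules, not the
  likelihood.
* Distances, not alignments, are the interface: the package trusts the
  homologous block it is given. `locate_primer()` helps find block
  bounds, but alignment quality is the user's problem.
* Likelihood-ratio p-values use a conventional chi-square reference; the
  threshold parameter's irregularity makes them conservative rather than
  exact.
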