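---
title: "Identifying and analysing physically clustered gene family members"
author: "GeneClusterKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and analysing physically clustered gene family members}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Gene families — sets of homologous genes produced by duplication — are often
arranged in tandem along a chromosome, because unequal crossing-over creates
new copies next to their template. Given a chromosome-level assembly and the
coordinates of one family's members, two questions arise:

1. **Which members are physically clustered**, i.e. closer together than
   uniform placement of the family across the genome would predict?
2. **Are clustered copies evolutionarily more similar to one another** than
   the family at large — as expected under recent tandem duplication or
   gene conversion?

GeneClusterKit answers both from minimal inputs: the genome size in Mb, a
BED or GFF3 file of family-member coordinates, and optionally a phylogeny of
the members (Newick with branch lengths in amino-acid replacements per
site), either supplied directly or inferred from a protein FASTA through
MAFFT plus FastTree/IQ-TREE.

## Cluster identification

Members on one scaffold, sorted by start coordinate, are chained whenever
the *intergenic gap* between consecutive genes is at most a threshold `g`
(bp). Maximal chains of two or more genes are clusters; the rest are
singletons. Because each of the `n − 1` consecutive gaps in an `n`-member
cluster is at most `g`, the summed intergenic span of a cluster never
exceeds the cutoff

```
C_L = g (n − 1).
```

Physical distance is defined as the gap of DNA between two loci —
`max(0, max(start_i, start_j) − min(end_i, end_j))` in half-open
coordinates — so overlapping or book-ended genes are at distance 0, and the
threshold reads directly as "at most `g` bp of DNA between neighbouring
copies". Distances between genes on different scaffolds are undefined and
reported as missing, never numeric. Strand is parsed and reported but plays
no role in clustering or distances.

### The null model behind g

How likely is it that two *unrelated* neighbours end up within `g` by
chance? If the `N` family members were placed uniformly at random on a
genome of `L` bp — a homogeneous Poisson process with rate `λ = N/L` —
adjacent gaps would be approximately exponential, and

```
p = P(adjacent gap ≤ g) = 1 − exp(−λ g).
```

`gapPValue()` computes `p` from `g`; `gFromPValue()` inverts it, so users
may specify either the threshold or the false-positive probability they are
willing to accept (`clusterParams()` enforces that exactly one is given).
The exact law for finite `N` uniform points is `1 − (1 − g/L)^N`; the
exponential form agrees with it to well below Monte-Carlo resolution
whenever `g ≪ L`, which is the regime the threshold is meant for (defaults:
`g` = 100 kb, a conventional scale in arthropod chemoreceptor studies,
against genomes of hundreds of Mb). The test suite verifies this
calibration against 10^5 uniform placements per family size over a grid of
(N, g) at a 1 Gb genome. No multiple-testing correction is applied: `p`
describes the threshold choice for one family, not a per-cluster test.

Note the model's assumptions: uniform gene density, no masking of repeats or
centromeres, and a single genome-wide rate. Families concentrated in
gene-dense or repeat-poor regions will look "clustered" partly for that
reason; `p` should be read as a calibration aid, not a significance test of
biology.

## Evolutionary analysis: the C_ST statistic

Given a phylogeny of the members, evolutionary distance between two genes
is their *patristic* distance — the sum of branch lengths on the path
between the leaves, independent of root placement. For each scope (one
scaffold, or the genome) with

* `D_T` = mean patristic distance over **all** unordered pairs in scope, and
* `D_C` = mean over pairs whose two genes share a cluster,

the statistic

```
C_ST = (D_T − D_C) / D_T
```

is the proportion of the family's genetic distance attributable to
unclustered genes: 0 when clustered copies are no more similar than average
(`D_C = D_T`), 1 when clustered copies are identical (`D_C = 0`), negative
if clustered copies are *more* divergent than average. It is reported as
missing, with a reason code, when `D_T = 0` or the scope has no
within-cluster pair. A Mann–Whitney U test compares the within-cluster pair
distances against all remaining pairs; per-scaffold scopes and the pooled
genome scope are reported side by side.

Two definitional choices were genuinely open and are logged in the run
metadata of every pipeline output:

* **D_C pools pairs across clusters** rather than averaging per-cluster
  means. Pooling weights each cluster by its pair count, which matches the
  U test's sampling unit (the pair); per-cluster averaging would up-weight
  small clusters.
* **The comparison set** for the U test is every pair *not* inside one
  cluster: singleton–singleton, singleton–clustered and cross-cluster
  pairs. This is the most inclusive reading of "unclustered" and keeps the
  two samples a partition of all pairs in scope.

The U statistic uses the exact null distribution when the smaller sample
has ≤ 8 pairs and no ties, and the tie-corrected normal approximation
otherwise; the test is two-sided by default with one-sided options.

### A caveat on the U test

Pairwise distances are not independent observations — two pairs sharing a
gene also share tree paths. Applied to distance pairs, the Mann–Whitney
test is therefore mildly anti-conservative: under a simulated null in which
cluster membership is independent of the phylogeny (20 genes, clusters of
2/3/5), its measured rejection rate at α = 0.05 is ≈ 0.08 rather than 0.05.
Interpret marginal p-values accordingly; strong signals (as produced by
recent tandem duplication) dwarf this inflation.

## Joint analysis of two families

Two families are clustered **independently**, each with its own `g`; their
gene identifiers are prefixed by the family label to keep the universes
disjoint. The joint report lists every same-scaffold pair of clusters whose
genomic spans intersect, with the intersection length in bp and the count
of genes of either cluster lying strictly inside the other's span
(interleaving). No cross-family chaining is performed and no co-evolution
statistic is computed — the joint view is exploratory.

## Coordinates and formats

BED (0-based half-open) and GFF3 (1-based inclusive) are both accepted and
converted exactly at parse time; internally loci live in a `GRanges` in the
Bioconductor 1-based closed convention, so the two encodings of one locus
are indistinguishable downstream, and BED write → read → write round trips
are byte-identical. GFF3 parsing selects rows by feature type (default
`gene`, overridable — annotations differ in whether receptors are typed
`gene` or `mRNA`) and takes the identifier from a configurable attribute
(default `ID`). A gene annotated as several rows under one ID is collapsed
to its minimal covering interval with a warning: clustering operates on
loci, not exon structure. Sorting is canonical — (scaffold, start, end,
gene id) — with the id as the deterministic tie-break.

## The synthetic-data generator

`simParams()` / `simulateFamily()` / `simulateTree()` generate seeded
fixtures with unambiguous ground truth, so every statistic above is
testable without any external dataset:

* **Placement.** True clusters (default sizes 2, 3, 5) and singletons
  (default 10) are laid out on equal-sized scaffolds (default 2 × 50 Mb);
  within-cluster gaps are drawn uniformly from 10–90% of the generating
  threshold (default 100 kb), unit separations from 2.5–6 × that threshold.
  Clustering at the generating `g` therefore recovers the construction
  exactly — by design, not approximately. Infeasible parameter sets fail
  before any file is written.
* **Trees.** With shrink `s = 1` the genes are assigned uniformly at random
  to the leaves of a random coalescent tree: cluster membership is then
  independent of the phylogeny, the appropriate exchangeable null for both
  C_ST (centred on 0) and the U test. With `s < 1`, a coalescent backbone
  over the units is rescaled to a mean pairwise distance of
  `evolBaseDistance` (default 1 replacement/site) and each cluster's members
  are grafted as a shallow star clade with expected within-cluster distance
  `s × evolBaseDistance`; the backbone terminal edge is shortened to
  compensate (floored at 1% of the base). A grafted construction at `s = 1`
  would equalise means but not distributions, which is why the null uses
  random assignment instead.
* **What it does not emulate.** Real gene density is not uniform; real
  within-cluster divergence is graded, not star-shaped; the dummy protein
  FASTA contains random sequences (for pipeline smoke tests only, not
  sequence evolution). Passing tests demonstrate correctness of the
  computations and calibration of the null model — not that any particular
  biological family is clustered.

The same seed yields byte-identical fixture files; each generator call uses
a private RNG stream and restores the caller's.

## Numerical and design choices

* Gap arithmetic in 1-based closed coordinates (`start₂ − end₁ − 1`,
  clamped at 0) is identical to the half-open formula; conversions happen
  only at I/O boundaries.
* Chain membership uses `gap ≤ g`, so a gap exactly at `g` clusters, and
  overlapping genes (gap 0) cluster at any positive `g`.
* `λ g > 50` is treated as a degenerate regime: `p` is reported as 1 with a
  warning rather than underflowing.
* Cluster ids are `"<family>_<scaffold>_c<k>"`, numbered left to right, so
  outputs are stable across runs.
* Figures: cluster-size spectra and physical-vs-evolutionary scatters are
  ggplot2; the triangular heatmap (physical distances in Mb below the
  diagonal, patristic distances above, cluster extents outlined on the
  diagonal, a second family's outlines in a second colour in joint mode) is
  drawn with base-graphics rasters. Palettes are colour-blind-safe
  (Okabe–Ito); physical distances are stored in bp and converted to Mb only
  at render time.
* The HTML report embeds every figure as a base64 data URI and inlines all
  tables: it renders with zero external fetches. A missing figure produces
  an inline warning block and a non-OK flag rather than a silent gap.
* The pipeline refuses to write into a non-empty output directory unless
  forced, materialises every default into `run_metadata.json`, and tags
  errors with input / consistency / external-tool condition classes (the
  CLI maps them to exit codes 2/3/4).

## Problem sizes in the test suite

The shipped tests run at deliberately modest scales chosen to make the
statistical checks decisive: 500 random instances of ≤ 12 genes against an
exhaustive chaining oracle; 10^5 uniform placements per family size for
null calibration; 200 seeded replicates each for the shrink-recovery
(s = 0.2) and null-size (s = 1) checks of C_ST and the U test; 100 random
8-leaf trees for root invariance. These sizes are properties of the test
design, and all expected values are either exact identities or computed by
independent oracles (enumeration, brute-force chaining, uniform
simulation).

## Known limitations

* The Poisson null assumes uniform gene density genome-wide; no correction
  for assembly gaps, repeats or chromosome-specific density is offered, and
  `g` is family-specific with no automatic selection procedure — the
  package exposes both `g → p` and `p → g` and leaves the choice to the
  user.
* The Mann–Whitney test on dependent pairwise distances is mildly
  anti-conservative (see above).
* Clusters never span scaffolds; a family split across an assembly break
  will be reported as separate clusters.
* `C_ST` compares means; it says nothing about which cluster drives a
  signal. Inspect the per-scaffold table and the heatmaps.
* External tree inference (MAFFT + FastTree/IQ-TREE) is a convenience
  wrapper over subprocesses; all statistics are computable from a
  user-supplied Newick file, which is the recommended route for publication
  analyses.
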