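# GeneClusterKit

Identification, statistical characterization and visualization of
**physically clustered gene-family members** in chromosome-level genome
assemblies.

Gene families — homologous genes born by duplication — are frequently
arranged in tandem arrays. Given nothing more than the genome size and the
family's coordinates (BED or GFF3), GeneClusterKit:

* identifies clusters by chaining members whose **intergenic gap ≤ g**
  (single linkage along each scaffold), so an *n*-member cluster spans at
  most **C_L = g(n − 1)** of intergenic DNA;
* calibrates the threshold with a **Poisson null**: under uniform placement
  of *N* members on an *L*-bp genome, adjacent gaps are ~exponential with
  rate λ = N/L, and the chance that a given adjacent pair sits within *g*
  is *p* = 1 − e^(−λg). Supply either *g* or the *p* you will tolerate —
  each determines the other;
* given a phylogeny of the members (Newick with branch lengths, or inferred
  via MAFFT + FastTree/IQ-TREE from a protein FASTA), contrasts physical
  and evolutionary organization with the **C_ST statistic**,

  C_ST = (D_T − D_C) / D_T,

  where D_T is the mean patristic distance over all member pairs in scope
  and D_C the mean over within-cluster pairs — 0 when clustered copies are
  typical, → 1 when clustered copies are (near-)identical — with a
  **Mann–Whitney U test** of within-cluster versus remaining pair
  distances, per scaffold and genome-wide;
* analyses **two families jointly** (independent clustering, spatial
  overlap and interleaving of their clusters);
* renders cluster-size frequency spectra, triangular physical/evolutionary
  distance heatmaps with cluster outlines, physical-vs-evolutionary
  scatter plots, and a **self-contained HTML report**;
* ships a seeded **synthetic-fixture generator** with known ground truth,
  so the whole pipeline is testable offline.

Audience: researchers studying gene-family evolution (chemoreceptors,
immunity genes, any medium-to-large family) in chromosome-level assemblies.

## Worked example

Simulate a 20-gene family (three true clusters of 2/3/5 plus 10 singletons
on a 100 Mb genome) whose clustered copies diverged five times less than
the family average, then analyse it:

```r
library(GeneClusterKit)

sp  <- simParams(seed = 42, withinShrink = 0.2)
sim <- simulateFamily(sp, dir = "fixture")          # writes BED/GFF3/FASTA
tree <- simulateTree(sim$truth, sp)

params <- clusterParams(sim$genome, length(sim$family), g = 1e5)
params
#> ClusterParams: g = 1e+05 bp, null p = 0.0198 (N = 20, genome = 100.0 Mb)

cs <- findClusters(sim$family, params)
cs
#> GeneClusterSet 'simfam': 3 cluster(s), 10 clustered + 10 singleton gene(s), g = 1e+05 bp
#>       cluster_id scaffold n first_start last_end span_bp
#>  simfam_scf01_c1    scf01 2      147500   173695   26196
#>  simfam_scf01_c2    scf01 3      452549   610559  158011
#>  simfam_scf01_c3    scf01 5     1100369  1279402  179034

cst <- computeCst(patristicMatrix(tree), cs)
print(cst[, c("scope","n_genes","n_clusters","D_T","D_C","C_ST","p")],
      digits = 3)
#>    scope n_genes n_clusters  D_T   D_C  C_ST        p
#> 1  scf01      14          3 1.08 0.188 0.825 6.63e-06
#> 2  scf02       6          0 1.06    NA    NA       NA
#> 3 genome      20          3 1.06 0.188 0.822 3.03e-05
```

Reading the output: at `g` = 100 kb the null probability that a random
adjacent pair falls within the threshold is ~0.02, so three recovered
clusters on one scaffold are far from chance arrangement. The genome-wide
C_ST of 0.82 says 82% of the family's mean genetic distance is contributed
by unclustered pairs — clustered copies are much more similar (D_C = 0.19
vs D_T = 1.06 replacements/site) — and the U test agrees (p ≈ 3 × 10⁻⁵).
Scaffold scf02 carries only singletons, so C_ST is undefined there and the
reason is reported. The 0.82 matches the generating shrink of 0.2 (within
distances ≈ 20% of base).

The full pipeline (tables, figures, HTML report, run metadata) is one call:

```r
runPipeline("fixture/family.bed", genomeSizeMb = 100, outDir = "results_demo",
            familyLabel = "simfam", g = 1e5, tree = "fixture/tree.nwk")
```

or, from a shell, via the thin wrapper in `inst/scripts/`:

```sh
Rscript inst/scripts/gene-cluster-tool.R evolve \
  --coords fixture/family.bed --genome-size-mb 100 --g-bp 100000 \
  --tree fixture/tree.nwk --out results_demo
```

Subcommands `cluster`, `evolve`, `joint`, `simulate`, `report`; exit codes
distinguish input (2), consistency (3) and external-tool (4) failures.

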