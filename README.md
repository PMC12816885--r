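# genusdemarc

Genome-based genus demarcation for prokaryotes: pairwise **AAI** and
**POCP** from per-genome proteomes, a data-driven AAI genus boundary
from the valley of a kernel density estimate, monophyly-constrained
grouping on a phylogenomic tree, **RED**-based rank harmonization, and
marker-gene/phenotype concordance (e.g. tryptophanase presence vs.
indole production) — plus a synthetic-data generator with planted
ground truth so every stage is testable.

It is written for microbial taxonomists and comparative genomicists who
want the genus-demarcation chain as reproducible, composable functions
rather than a pile of one-off scripts around external tools.

## The statistics at the core

* **AAI** — mean percent identity over reciprocal best-hit protein
  pairs between two proteomes, with hits filtered at identity ≥ 40%,
  query coverage ≥ 50% (both directions) and e-value ≤ 1e-5.
  Alignments are exact Smith–Waterman (BLOSUM62, gap open 11 /
  extend 1); e-values use the Karlin–Altschul form
  E = K·m·n·exp(−λS) with λ = 0.3176, K = 0.134.
* **POCP** — 100·(C1+C2)/(T1+T2), where T1, T2 are the proteome sizes
  and C counts proteins with at least one hit in the other genome at
  e-value < 1e-5, identity > 40% and an alignable region > 50% of the
  query length. The common genus criterion is POCP ≥ 50%.
* **AAI boundary** — Gaussian KDE of the pooled pairwise AAI values
  (bandwidth 0.9·min(sd, IQR/1.34)·n^(−1/5), 512-point grid, computed
  by exact direct summation); the boundary is the lowest qualifying
  interior local minimum in the 60–80% window, with a sensitivity
  sweep of the bandwidth multiplier over 0.5–2.0. Candidate minima
  must separate ≥ 5% of the density mass on each side and dip ≥ 40%
  below the smaller flanking peak, which rejects sampling wiggles.
* **Genus groups** — genomes joined when a pair passes *both*
  AAI ≥ boundary and POCP ≥ 50; connected components are tested for
  monophyly on a rooted tree, and non-monophyletic components shed
  members greedily (with reason codes) until monophyletic.
* **RED** — relative evolutionary divergence, red(n) = red(p) +
  (1 − red(p))·d/u (root 0, leaves 1), used to compare the depth of
  proposed genera against established neighbours.

See the methods vignette (`vignettes/genus-demarcation.Rmd`) for the
full model, parameter and design discussion.

## Worked example

Generate a synthetic set of 10 genomes (2 planted genera × 5 genomes,
150 protein families; within-genus crown identity ≈ 85%, between-genus
identity ≈ 70%) and run the whole chain:

```r
library(genusdemarc)

ds <- simulate_dataset(sim_config(seed = 1))
report <- run_pipeline(run_config(
  proteomes = ds$proteomes, tree = ds$tree,
  marker = list(gtree = ds$marker$gtree,
                phenotype = ds$marker$phenotype)))
report
#> <run_report>
#> <threshold_estimate> minimum at 78.13 (sweep 77.68-78.58, 1 mode(s) in [60, 80])
#> <genus_partition> 2 group(s), 0 excluded (AAI >= 78.13, POCP >= 50)
#>   group1: g1_s01, g1_s02, g1_s03, g1_s04, g1_s05
#>   group2: g2_s01, g2_s02, g2_s03, g2_s04, g2_s05
#>   median group RED: 0.572
#> <concordance_table> agreement 1.000 over 10 genomes (n11=5 n10=0 n01=0 n00=5; absent/neg=0 absent/pos=0)
```

Reading the output: the pooled AAI distribution of the 45 genome pairs
has its valley at **78.1%** (stable across the bandwidth sweep:
77.7–78.6%), which cleanly separates the planted between-genus
comparisons (mean AAI 69.9%) from the within-genus ones (mean 86.7%).
Joint AAI/POCP edges plus the monophyly constraint recover exactly the
two planted genera with no genome excluded; both genus crown nodes sit
at RED ≈ 0.57 on this two-clade tree; and marker-clade membership
matches the planted phenotype for all 10 genomes (agreement 1.0).

Individual stages are ordinary functions if you want them piecemeal:

```r
m   <- pair_metrics(ds$proteomes)     # genome_a, genome_b, aai, pocp, ...
est <- bandwidth_sweep(m$aai)         # threshold estimate + sweep
prt <- delineate(ds$tree, build_graph(m, est$minimum_at, 50))
red <- compute_red(ds$tree)
```

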