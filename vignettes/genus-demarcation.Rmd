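---
title: "Genome-based genus demarcation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based genus demarcation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genusdemarc)
```

## The problem

Prokaryotic genera are increasingly delimited from whole-genome
signatures rather than from phenotype alone. Two pairwise metrics carry
most of the weight: the **average amino acid identity** (AAI), the mean
percent identity over reciprocal best-hit protein pairs between two
proteomes, and the **percentage of conserved proteins**
(POCP = 100·(C1+C2)/(T1+T2), where T is the proteome size and C counts
proteins with a qualifying hit in the other genome). A commonly used
genus criterion is POCP ≥ 50%; AAI has no universal genus threshold, so
a data-driven boundary is estimated from the shape of the pooled AAI
distribution: when the distribution of pairwise AAI values across a
group of related genomes is bimodal, the valley between the two modes
separates within-genus from between-genus comparisons. Candidate genera
are then required to be monophyletic on a phylogenomic tree, and the
**relative evolutionary divergence** (RED) of the resulting clades is
compared against the typical depth of established genera to check that
the proposed ranks are not aberrant. Finally, a discrete marker —
presence of a functionally validated tryptophanase (*tnaA*) lineage,
matched against the indole-production phenotype — can corroborate a
split.

This package implements that entire chain as composable, deterministic
functions, together with a synthetic-data generator that plants known
genus structure so every stage can be tested against ground truth.

## Pairwise metrics

### Alignment engine

All protein-versus-protein comparisons use an in-package Smith–Waterman
implementation (BLOSUM62; affine gaps with open 11, extend 1, so a gap
of length L costs 11 + L). Alignment is exact dynamic programming, not
a heuristic seed-and-extend search: at the scale this package targets
(simulated or down-sampled proteomes) exactness and determinism are
worth more than speed, and there is no external binary dependency.
Traceback is deterministic (diagonal preferred over a gap in the
subject, preferred over a gap in the query; the best local cell is the
first maximum in row-major order), so identities — which depend on the
chosen co-optimal alignment — are reproducible bit for bit. Gap
penalties are required to be whole numbers; the batch search exploits
this with an integer DP.

E-values use the Karlin–Altschul form E = K·m·n·exp(−λS) with the
classical ungapped constants λ = 0.3176, K = 0.134 applied to the
gapped score. This is an approximation (gapped statistics would need
their own fitted constants); it is documented, fixed, and used only as
a hit filter, where what matters is a consistent, monotone transform of
the score and the sequence lengths.

### Filters

AAI averages identities over reciprocal best hits passing identity
≥ 40%, coverage ≥ 50% of the query in both directions, and e-value
≤ 1e-5 in both directions (inclusive comparisons). POCP counts a
protein as conserved if *any* hit in the other proteome satisfies
e-value < 1e-5, identity > 40% and an alignable region > 50% of the
query length (strict comparisons, following the published POCP
definition; the coverage denominator is the query length, not the
subject). The two filter sets deliberately differ in strictness of the
inequalities; boundary cases are unit-tested. When no reciprocal best
hit passes, the AAI is reported as undefined with an explicit flag —
never as a silent `NaN` — and such pairs contribute no edge downstream.

Because the optimal local alignment and its score are symmetric in the
two sequences, the all-versus-all search is run once per unordered
genome pair and both search directions are derived from the same score
and alignment matrices; AAI and POCP are therefore exactly symmetric.

A marker-subset AAI (`marker_aai()`) averages *global* alignment
identities over marker genes present as single copies in both genomes,
for analyses that recompute AAI from a fixed panel of conserved
single-copy genes. The marker panel is an input (a genome → marker →
protein map); no panel is hard-coded.

## Boundary detection

`kde()` pins the conventional defaults of R's density estimator
operationally: Gaussian kernel, bandwidth 0.9·min(sd, IQR/1.34)·n^(−1/5)
(times an `adjust` multiplier), 512 grid points spanning the data
extended by 3 bandwidths. The density is computed by *direct summation*
at every grid point rather than by binned FFT approximation, so the
curve is exact to machine precision and tests can compare it against an
independent direct sum at 1e-9 relative tolerance.

`local_minimum()` searches a window (60–80% AAI by default) for the
lowest interior grid point that is ≤ both neighbours, with ties broken
toward the lower abscissa. Two guards separate genuine between-mode
valleys from sampling artefacts:

* **mass**: each side of a qualifying minimum must hold at least 5% of
  the curve's total probability mass. A genus boundary must separate a
  non-trivial fraction of the pairwise comparisons; without this,
  near-empty density tails produce spurious minima at small bandwidths.
* **prominence**: the minimum's density must lie at or below 60% of the
  smaller of the two flanking density maxima, taken over the *full*
  curve (a mode may legitimately sit outside the search window).
  Shallow shoulders on the flank of a single mode are sampling noise;
  in measured well-separated mixtures the genuine valley sits at
  19–30% of the smaller peak, while unimodal-sample shoulders rarely
  dip below 60%, so the threshold sits at about twice the worst
  genuine ratio.

`bandwidth_sweep()` repeats the search for adjust = 0.5, 0.6, …, 2.0
(the stated range, stepped at 0.1 — 16 evaluations, fine enough to
bound the interval) and reports the range of detected minima; the
working estimate is the adjust = 1 minimum. If no bandwidth yields a
qualifying minimum the estimate carries a no-boundary flag, which is
the expected outcome for distributions without a clear bimodal pattern
(as POCP often is).

Input values are the pooled AAI values over unique unordered pairs
(each pair counted once); this is the convention implied by the
symmetry of the metrics.

## Clade delineation

`build_graph()` connects genome pairs satisfying *both* criteria
(AAI ≥ boundary and POCP ≥ 50, inclusive). Groups are the connected
components of this graph — the simplest faithful reading of "grouping
the pairs that meet both criteria"; a clique-based rule would be
stricter and is deliberately not used, since single failing pairs
inside an otherwise coherent group would then shatter it.

Each component is tested for monophyly on the rooted species tree (the
leaves under the component's MRCA must be exactly the component;
singletons are monophyletic by definition). A non-monophyletic
component is resolved by greedy removal: the member whose removal most
reduces the intruder count is excluded (ties broken by removing the
lexicographically last id), and because a removal can disconnect the
criterion subgraph, the survivors are re-split into criterion-connected
components before re-testing. This makes `delineate()` idempotent on
its own output. Exclusions carry a reason code so the behaviour is
auditable — the underlying decision ("excluding some genomes that break
monophyly") is in reality often made by inspection, and the greedy rule
is an explicit, reproducible stand-in.

Trees are taken as rooted at the outermost Newick node; no re-rooting
is attempted, and multifurcations (including at the root) are handled
natively throughout.

## Relative evolutionary divergence

RED linearly interpolates node depth between the root (0) and the
leaves (1): for node n with parent p,
red(n) = red(p) + (1 − red(p))·d/u, where d is the branch length from p
to n and u the mean branch length from p to all leaves descending
through n. Leaves are 1 by definition; a zero-length internal branch
gives the child its parent's RED; an internal node whose entire subtree
(including its own branch) is zero-length makes the recursion undefined
and raises an error naming the node. RED is invariant under global
branch-length scaling and non-decreasing along root-to-leaf paths; both
properties are asserted in tests against an independent recursive
reference implementation.

The RED of a taxon is the RED of the MRCA of its members. For singleton
taxa the parent node's RED is returned with an explicit flag rather
than interpolating along the pendant edge — conservative and visible,
where interpolation would manufacture precision. `rank_summary()` takes
the median over taxa (even counts: mean of the central pair);
`core_clade_red()` evaluates the smallest clade containing a named
subset (e.g. the validly published species of a proposed genus), which
is never shallower than the full group's node.

## Marker–phenotype concordance

The validated clade of a gene tree is the MRCA of the
experimentally validated reference sequences — the minimal defensible
formalization of a clade drawn around reference genes in a figure. A
genome is a member if at least one of its genes falls under that node;
genomes whose genes all fall outside are `FALSE`, while genomes with no
gene in the tree are *absent* from the membership map — marker absence
in a phenotype-negative genome corroborates rather than contradicts the
marker hypothesis, so those genomes are tallied separately instead of
entering the agreement count. Phenotypes may be three-valued
(positive/negative/variable); "variable" genomes — a real annotation
state for indole production in this family — are excluded from counts
by default.

## The synthetic generator

The generator emulates the statistical structure the pipeline is built
to detect, with closed-form truth tables:

* **Tree** (`simulate_tree()`): an ultrametric species tree;
  each genus is a random coalescent subtree, and all between-genus
  pairs sit at distance `inter_depth` exactly. `intra_depth` is the
  *crown* divergence: the deepest within-genus pair. Coalescence depths
  are pulled toward the crown (`crown_shape = 0.2`), concentrating
  within-genus identities near the planted crown identity; with raw
  coalescent depths, within-genus identities smear from the crown value
  all the way to ~100%, which leaves the AAI valley shallow and
  ill-defined at the default bandwidth.
* **Proteomes** (`simulate_proteomes()`): each of `n_families` families
  starts from a uniformly random root sequence and evolves by per-site
  Poisson substitutions with uniform replacement among the other 19
  amino acids. Under this model the expected identity at pairwise
  distance d is 5 + 95·exp(−d·20/19) — the 5% floor is the
  random-alignment baseline of a 20-letter alphabet — and this closed
  form populates the truth table. Families are lost irreversibly per
  branch with probability `loss_prob_per_branch` (default 0.02), the
  simplest mechanism that pushes POCP below 100 with an analyzable
  expectation.
* **Marker** (`simulate_marker()`): the marker gene evolves on the
  carrier clade's induced subtree with reference sequences grafted at
  the carrier crown (so the references' MRCA circumscribes exactly the
  carriers); non-carrier genomes receive a distant paralog in a sister
  clade, so their membership is `FALSE` rather than missing. The
  phenotype equals carriage, with optional planted discordance.

Default conditions: 2 genera × 5 genomes, 150 families of 50 aa,
within-genus crown identity ≈ 85%, between-genus identity ≈ 70%. The
default `inter_depth` (0.3812 substitutions/site) is calibrated so that
the *realized* AAI lands at the planted 70%: local alignment trims
poorly matching ends, which inflates AAI by about +1.4 points over the
raw expected site identity at that distance. Family count and length
are a deliberate desk-scale choice: 150 × 50 aa gives per-pair AAI
standard errors of about 0.5 points — small against the 15-point
planted mode separation — while keeping a full 10-genome, 45-pair run
in the tens of seconds.

Identical configurations (including the seed) produce byte-identical
outputs; all randomness flows through the single seed.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: indels (family members stay
equal-length, so identity bookkeeping is alignment-free);
across-site and across-lineage rate variation; an empirical amino acid
replacement matrix (uniform replacement keeps the identity–distance
curve closed-form; BLOSUM-like exchangeabilities would raise alignment
scores at equal identity); paralogy and horizontal transfer in the
proteomes (every family is single-copy, so reciprocal best hits are
trivially correct orthologs); genome incompleteness and annotation
error. Real AAI distributions are also mixtures over many more,
unevenly sampled taxa; the planted two-mode structure is the cleanest
instance of the shape the boundary detector targets, not a model of
sampling bias.

## Numerical and degenerate-input choices

* Thresholds on AAI/POCP edges are inclusive (≥); POCP's internal hit
  filters are strict (>) per its published definition.
* KDE requires ≥ 3 finite values with nonzero spread (the bandwidth is
  otherwise undefined and the function errors rather than guessing);
  if the quartiles coincide but the spread is nonzero, the bandwidth
  falls back to the standard-deviation term, mirroring the behaviour
  of the classical rule.
* Duplicate FASTA ids, duplicate pair rows, unknown tips, gapped
  proteome input and unbalanced Newick are hard errors naming the
  offending record, pair, tip or offset.
* `aai(a, a)` = 100 and `pocp(a, a)` = 100 exactly; identity 100 occurs
  iff the aligned sequences are identical.
* Nucleotide global identity uses match +1, mismatch −1, gap 2 per
  column, identity = matches / all alignment columns (gap columns in
  the denominator) — deterministic and symmetric. Published 16S
  similarity values computed with other aligners and identity
  conventions can differ from these by a few tenths of a percent, so
  small deviations are expected when comparing against reported
  numbers.
* In the pipeline, "auto" thresholding requires ≥ 10 defined pairwise
  AAI values and aborts with a clear message when no boundary
  qualifies; a fixed threshold can always be supplied instead.

## Interfaces

The package's functions are the interface: `pair_metrics()` →
`bandwidth_sweep()` → `build_graph()`/`delineate()` → `compute_red()`
→ `concordance()`, orchestrated by `run_pipeline()` with a single
`run_config()`. All tabular intermediates read and write TSV, reports
write versioned JSON, and `simulate_dataset()` can materialize a
complete run directory (FASTA/Newick/TSV/JSON) for file-based runs.
`scripts/acceptance.R` is a thin command-line wrapper that regenerates
the default synthetic conditions and reruns the whole chain.

## Known limitations

The exact dynamic-programming search is quadratic in sequence length
and all-vs-all in family count; full-size bacterial proteomes
(~3,000 proteins × ~300 aa) are outside its comfortable range, and
swapping in an external search tool for such runs would require
adapting `pair_alignments()`. RED comparisons against reference
taxonomies (e.g. phylum-wide genus medians) require the external
reference tree as input; the package computes the statistic but ships
no reference data. The greedy monophyly-exclusion rule is a stand-in
for expert curation: it is deterministic and auditable, but on
pathological graphs it need not find the minimal exclusion set.
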