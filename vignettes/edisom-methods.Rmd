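---
title: "Methods: supra-hexagonal SOM clustering of staged expression profiles"
author: "edisom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supra-hexagonal SOM clustering of staged expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edisom)
```

## The problem and the model

The package analyses a transcript-by-condition table of linear-scale
expression intensities with one designated control column and an ordered
series of treatment-stage columns, the design that arises when a cell
population is profiled at consecutive stages of a staged intervention
(e.g. escalating-dose immunotherapy) against a vehicle-treated control.
The analysis asks a pattern question, not a per-gene testing question:
which transcripts share a temporal regulation trajectory, what are the
dominant trajectories, and what biology do they carry?

The core model is a self-organizing map (SOM): a lattice of units, each
holding a codebook vector in the profile space (here, length-`S` vectors
of stage-wise log2 fold changes). Training pulls the codebooks toward the
data while the lattice's neighbourhood structure keeps nearby units
similar, so the trained map is a topology-preserving, locally smooth
quantization of the profile distribution. Clusters are then read off the
map's own geometry rather than imposed: basins of the neighbour-distance
surface become clusters, with no cluster count assumed in advance. This
two-phase design (vector quantization, then topological segmentation) is
what distinguishes the approach from k-means or hierarchical clustering
applied directly to profiles: the map absorbs noise at the unit level, and
the segmentation sees the *density structure* of the codebooks, not the
raw points.

### Assumptions

* Intensities are already normalized across arrays and on a linear scale.
  Log2-scale input must be declared (`log2_input = TRUE` in
  `read_expression_table()`), in which case it is exponentiated before
  flooring, because the detectability floor is defined in linear units.
* The control column is a valid common reference for every stage; fold
  changes are computed against it only.
* No missing values; the table is complete.
* Profiles are comparable on the raw log2FC scale. Profiles are *not*
  row-standardized before training: component planes are meant to display
  the signed magnitude of regulation, and standardization would make a
  0.1-fold wiggle look like a 4-fold swing.

## Preprocessing

**Detectability floor** (`apply_floor()`, default 200 intensity units):
values strictly below the floor are clamped up to it, in control and
treatment columns alike, so a ratio of two undetectable values is exactly
1 and can never generate spurious fold change. The boundary convention —
clamp strictly-below, leave exactly-200 standing — is immaterial for
ratios because the clamp maps the ambiguous region to a single point.
Re-flooring a floored matrix errors rather than silently no-opping, since
a silent second application usually indicates a pipeline wiring mistake.

**Regulation filter** (`regulation_filter()`, defaults `min_fold = 2`,
`min_stages = 4`): a transcript is kept iff `|log2FC| >= log2(min_fold)`
at `min_stages` or more stages. The bound is inclusive ("two-fold or
greater") and two-sided, since repression trajectories are as informative
as induction. The filter is monotone in both parameters (tightening never
enlarges the kept set) and invariant to row order; both properties are
tested.

## Map fitting

**Geometry.** The lattice is supra-hexagonal: a hexagon-shaped arrangement
of hexagonal units, `r` rings holding `3r(r-1)+1` units. Axial coordinates
`(q, r)` map to unit centres `x = q + r/2`, `y = r*sqrt(3)/2`, making
lattice neighbours exactly distance 1 apart; all lattice distances are
Euclidean on these centres. When the ring count is not given it is chosen
by scanning `r = 1..50` for the unit count closest to `5*sqrt(N)` (ties to
the smaller map) — the standard map-sizing heuristic, which for example
assigns a 9-ring, 217-unit map to 1,893 profiles.

**Initialization.** Codebooks are initialized linearly on the plane
spanned by the data's first two principal directions: unit coordinates,
normalized to `[-1, 1]` per axis, are mapped to
`mean + x*sd1*PC1 + y*sd2*PC2`. PCA signs are fixed (largest-magnitude
loading positive) so the initialization is fully deterministic. If the
data are rank-deficient (fewer than 3 rows, or a second singular value
below 1e-10) the fallback is seeded uniform initialization inside the
per-stage data range.

**Training** (`suprasom()`). The neighbourhood kernel is Gaussian,
`h(c,i) = exp(-d(c,i)^2 / (2*sigma^2))` with `d` the lattice distance.
The default schedule has two phases: a rough ordering phase of
`max(5, ceiling(10 * units / N))` epochs with `sigma` shrinking linearly
from the grid radius `r` to 1, then a fine-tuning phase four times as long
with `sigma: 1 -> 0.5`. In batch mode (default) each epoch recomputes
every codebook as the `h`-weighted mean of all profiles given the current
BMU assignment; this is deterministic given the data, independent of the
seed. Sequential mode applies the classic update
`m <- m + alpha*h*(x - m)` in a seeded random sample order with learning
rates 0.5 -> 0.05 (rough) and 0.05 -> 0.01 (fine); it exists mainly for
completeness and for didactic single-step tests. With `sigma` far below
the unit spacing the batch update degenerates to Lloyd's k-means step, and
the test suite verifies that quantization error is non-increasing per
epoch in that limit.

**Numerical guards.** BMU ties break to the lowest unit index
(`ties.method = "first"`), making assignments reproducible on degenerate
codebooks. Batch denominators below 1e-300 (a unit receiving no weight,
impossible with a true Gaussian but reachable through underflow at tiny
`sigma`) leave that codebook unchanged for the epoch.

## Topological partition

`neighbor_distance()` computes the U-height of each unit: the mean
Euclidean codebook distance to its lattice neighbours (units at distance
1; boundary units average over the neighbours they have; an isolated unit
scores 0). `find_seeds()` takes units whose height is `<=` every
neighbour's height; a connected plateau of equal-height adjacent minima
(equality to a relative tolerance of 1e-9) collapses to its lowest-index
unit, so flat regions yield one seed, not one per unit. `som_partition()`
then grows clusters: repeatedly, among unassigned units adjacent to any
assigned unit, attach the one whose codebook is closest to the adjacent
cluster's **seed** codebook (ties: lower cluster ID, then lower unit
index). Comparing to the seed rather than a running centroid keeps the
partition a pure function of the trained map — no incremental state, no
order-dependent drift — at the cost of slightly less adaptive boundaries.
Clusters are renumbered 1..K by seed unit index, transcripts inherit their
BMU's cluster, and each cluster's representative pattern is its seed
codebook, reported verbatim.

The cluster count is emergent. `max_clusters` optionally caps it by
iteratively merging the two clusters with the closest seed codebooks; the
cap exists for display purposes and is off by default, because a cluster
count is a *result* of this analysis, not an input.

## Component planes and reports

`component_planes()` re-lays the codebook as one map per stage (plane `k`
colours unit `u` by `codebook[u, k]`). All planes share symmetric colour
limits `(-m, +m)`, `m = max|codebook|`, so colour is comparable across
stages; an all-zero codebook widens the degenerate `(0, 0)` limits to
`(-1, 1)`. The palette is a continuous diverging blue-white-red map
anchored at 0 log2FC (red = induced, blue = repressed). Planes are also
exported as plain TSV matrices so rendering is optional and tests are
image-free. `gene_panel_report()` assembles a per-gene stage-wise
fold-change table for a chosen panel, marking genes that failed the
regulation filter (hence were never clustered) with a hyphen.

## Enrichment

`enrich_clusters()` performs over-representation analysis per cluster and
term: overlap `k`, term size `K` and cluster size `n` are all computed
within the background universe of size `N`, the p-value is the exact
hypergeometric upper tail `P(X >= k)` (via `phyper`; the suite checks it
against explicit binomial-coefficient enumeration for every parameter set
with `N <= 25`), and q-values are BH step-up adjusted **within each
cluster x namespace family** — per-cluster term lists per ontology are the
reporting unit, and adjusting globally across clusters would couple
unrelated lists. The default background is every gene carrying at least
one annotation in the namespace; it can be switched to the filtered gene
set (`background = "filtered"` in the pipeline config), which is more
conservative when annotations cover far more genes than the array. Rows
with overlap `>= 3` and `q < 0.05` are flagged `reported`; all rows are
returned either way, and the reported set provably shrinks as either
threshold tightens. Gene matching is exact-string; identifier translation
is a data-preparation concern outside the package.

## The synthetic generator

`simulate_expression()` emulates the statistical structure the pipeline
assumes, with ground truth attached:

* **Five archetypes** (`archetype_profiles()`): fixed piecewise-linear
  unit-amplitude shapes — repressed from baseline, repressed after initial
  induction, incrementally induced, induced-then-repressed,
  induced-and-maintained — sampled at the stage positions. Shapes are
  fixed rather than sampled so the recovery surface is reproducible. Their
  transitions are deliberately fast relative to the stage grid: a
  unit-amplitude pattern scaled by the default amplitude of 1.5 log2 units
  keeps most stages beyond the two-fold threshold, so a regulated gene
  fails the filter only through unlucky noise or a sub-floor baseline.
  With per-stage Gaussian noise of sd 0.25, a stage planted at 1.5 log2
  units clears the threshold with probability ~0.98, and the per-archetype
  probability of reaching 4 qualifying stages is 0.94-0.999.
* **Baselines**: control intensities are lognormal with
  `meanlog = log(500)` (mean intensity about 500) and `sdlog = 0.1`. The
  spread is kept narrow on purpose: sub-floor behaviour is modelled by the
  explicit `sub_floor_fraction` knob (default 0.05, drawn uniformly in
  `[25, 199]`), and a wide lognormal would additionally push the deeply
  repressed stages of low-baseline genes under the floor, making the
  floor's effect depend on the tail of the baseline distribution rather
  than on the documented parameter. Real array intensities span far wider
  ranges; see limitations.
* **Noise** is additive on the log2FC scale, i.e. multiplicative on
  intensities — matching how the pipeline consumes the data. Stage
  intensities are `control * 2^(amplitude*shape + noise)`; null genes get
  noise only; the matrix is emitted unfloored.
* **Companion gene sets** (`synthetic_gene_sets()`): one GMT term per
  archetype holding its true members plus 20% null-gene decoys, so the
  enrichment stage has a known correct answer.

`recovery_score()` evaluates recovery as the adjusted Rand index between
planted labels and the clustering *after merging clusters by majority
archetype*: the map legitimately splits one archetype across adjacent
basins, and the merge scores the biology (are archetypes separated?)
rather than the granularity. Under the default conditions (100 genes per
archetype, 500 nulls, amplitude 1.5, noise sd 0.25) the full pipeline
recovers the archetypes with median ARI about 0.98, filter sensitivity
about 0.93 and a null pass rate of essentially zero — numbers recomputed,
not quoted, by the test suite and `scripts/acceptance.R`.

What the generator does **not** emulate: probe-level array physics, batch
or chip effects, correlated noise across stages, heavy-tailed intensity
distributions, annotation incompleteness, or biological overlap between
pattern groups. Passing the recovery tests therefore demonstrates that the
implementation resolves well-separated planted structure under its own
assumptions — not that it will resolve arbitrarily subtle structure in
real data.

A second generator, `simulate_deposited_matrix()`, produces a synthetic
stand-in shaped like a deposited clustered supplementary matrix (1,893
transcripts, control plus six stages, 12 cluster labels with cluster 2
holding nine transcripts) for format and reconciliation tests; it is
labelled synthetic throughout and is not the deposited data.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on
1,000-gene simulations (about 470 filtered genes, a 7-ring / 127-unit
map), 5 seeds for recovery and 10 for filter operating characteristics —
sizes chosen so the whole suite completes in seconds while leaving the
per-seed sampling error on the reported medians well below the margins of
the thresholds being checked. Every stochastic step takes an explicit
seed; batch training and the partition are deterministic given the data,
so `run_pipeline()` with a fixed config and seed reproduces its output
bundle byte for byte (the manifest records MD5 hashes to make this
checkable).

## Known limitations

* The exact training schedule and merging rules of the SOM toolchains
  used in published staged-immunotherapy analyses are not fully public;
  this package states its own schedule and growth rule explicitly, and an
  emergent cluster count on real deposited data need not equal a published
  count obtained with different internals.
* Seed-codebook growth can misallocate boundary units between two large
  adjacent basins when the seed sits far from the shared border.
* Enrichment treats terms as flat sets: no ontology-graph propagation,
  no term-redundancy reduction.
* The filter is a hard threshold; transcripts regulated strongly at three
  stages and weakly elsewhere are excluded by design, as in the original
  filtering rule.
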