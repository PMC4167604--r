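# edisom

Clustering and interpretation of gene-expression **time courses measured
against a single control**, as produced by staged treatment designs — the
motivating case is CD4+ T-cell transcriptomes sampled at consecutive stages
of escalating-dose peptide immunotherapy, profiled on arrays against a
PBS-treated control. The package is for analysts who have a normalized
transcript-by-condition intensity table and want to know *which groups of
transcripts move together across the stages, what their shared temporal
pattern is, and which functional terms each group is enriched for*.

## Method

Given linear-scale intensities for `G` transcripts across a control and `S`
treatment stages:

1. **Detectability floor.** Intensities below an empirical floor (default
   200) are not reliably discriminated from noise; every value `x < 200` is
   clamped to 200 before any ratio is formed.
2. **Regulation filter.** Per transcript `g` and stage `s`,
   `fc(g,s) = log2( I(g,s) / I(g, control) )`. A transcript enters the
   analysis set iff `|fc(g,s)| >= log2(2)` at `>= 4` stages (both
   thresholds configurable; the bound is inclusive and two-sided, so
   two-fold repression counts as much as two-fold induction).
3. **Supra-hexagonal SOM.** The filtered `log2FC` profiles are fitted with
   a self-organizing map on a hexagon-shaped lattice of hexagonal units
   (`r` rings hold `3r(r-1)+1` units; `r` is sized so the unit count tracks
   `5*sqrt(N)`). Training uses the Gaussian neighbourhood kernel
   `h(c,i) = exp(-d(c,i)^2 / (2*sigma^2))` on lattice distances, with a
   rough phase (`sigma: r -> 1`) followed by a fine-tuning phase
   (`sigma: 1 -> 0.5`), batch updates by default. Each transcript maps to
   its best-matching unit (BMU), the unit with the nearest codebook vector.
4. **Topological partition.** The trained map is segmented with no preset
   cluster count: units that are local minima of the neighbour-distance
   (U-height) surface become *seed units*; clusters grow outward over the
   lattice, each unassigned frontier unit joining the adjacent cluster
   whose seed codebook it is closest to. Transcripts inherit their BMU's
   cluster, and each cluster's representative expression pattern is its
   seed unit's codebook vector.
5. **Component planes.** One recoloured copy of the map per stage (unit
   value = that stage's codebook component, shared symmetric colour scale),
   showing how regulation redistributes over the map as treatment
   progresses.
6. **Enrichment.** Per cluster and term (flat GMT gene sets), the exact
   hypergeometric upper tail `P(X >= k)` for an overlap of `k` in a
   background of `N` genes, BH-adjusted within each cluster x namespace
   family; rows with overlap `>= 3` and FDR `< 0.05` are flagged as
   reported.

A synthetic generator (`simulate_expression()`) plants five canonical
temporal archetypes — repressed from baseline, repressed after initial
induction, incrementally induced, induced-then-repressed and
induced-and-maintained — over lognormal baselines with sub-floor values and
Gaussian log-scale noise, with ground-truth labels, so the entire pipeline
is testable against a known answer (`recovery_score()` gives the adjusted
Rand index after merging clusters by majority archetype).

## Worked example

```r
library(edisom)
sim  <- simulate_expression(synthetic_spec(seed = 1))   # 500 regulated + 500 null genes
expr <- apply_floor(sim$expr, floor = 200)
fc   <- fold_change(expr)
filt <- regulation_filter(fc, filter_rule(min_fold = 2, min_stages = 4))
sum(filt$report$kept)
#> [1] 478
fit  <- suprasom(filt$fc, seed = 1)
fit
#> Supra-hexagonal SOM (7 rings, 127 units, 6 stages)
#>   mode: batch | quantization error: 0.2837 (init 1.327)
part <- som_partition(fit)
summary(part)
#>  cluster seed_unit transcripts
#>        1        38          97
#>        2        48          67
#>        3        68          71
#>        4        81          96
#>        5        88          94
#>        6       101          23
#>        7       105          30
enr <- enrich_clusters(part, synthetic_gene_sets(sim$truth, seed = 1))
head(enr[order(enr$q_value), c("cluster", "term_id", "overlap", "q_value")], 3)
#>  cluster                term_id overlap      q_value
#>        4          SYN:repressed      96 1.130533e-87
#>        1 SYN:induced_maintained      96 1.044207e-85
#>        5        SYN:incremental      92 5.586192e-79
recovery_score(sim$truth, part)
#> [1] 0.984
```

Of the 1,000 simulated genes, 478 pass the two-fold-at-four-stages filter
(nearly all of them planted regulated genes). The map resolves 7 clusters;
several archetypes split over two adjacent map clusters, which the
majority-archetype merge in `recovery_score()` absorbs, giving an adjusted
Rand index of 0.98 against the planted truth. Each planted term surfaces as
the top enrichment of the cluster holding its genes. `plot(fit)` draws the
per-stage component planes; `plot(fit, type = "uheight")` the seed
landscape; `run_pipeline()` executes the whole sequence from a YAML config
and writes a deterministic TSV bundle (see `inst/scripts/edisom.R` for the
command-line front end).

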