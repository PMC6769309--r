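# topohet — topological quantification of transcriptome heterogeneity

`topohet` asks whether the samples of one phenotype group are more dissimilar
to *each other* — transcriptome-wide — than the samples of a matched control
group. The question matters for clinically heterogeneous disorders, where
patients may share no common expression signature yet differ from controls in
how scattered their expression profiles are. Differential expression cannot
see this; the geometry of the sample cloud can.

## The method

Each group's samples form a point cloud with dissimilarity `1 − r`
(`r` = Pearson correlation of expression profiles). Persistent homology with
Z/2 coefficients tracks the cloud's topological cycles across a growing scale
`ε` (Vietoris–Rips filtration): every cycle gets a birth and a death scale.
Two diagram summaries quantify the cloud:

* **SDT₀** — the sum of death times of the connected components. Points of a
  dispersed cloud merge late, so SDT₀ grows with heterogeneity; it equals the
  total minimum-spanning-tree weight, and the package computes it exactly by
  union-find without the full reduction.
* **χ = SL₀ − SL₁ + SL₂** — the Euler characteristic of the diagram, an
  alternating sum of total cycle lengths over dimensions 0–2.

The group difference `D = invariant(case) − invariant(control)` is tested by
re-partitioning the pooled samples into random equal halves and recomputing
`D` from scratch each time; the reported *permutation FDR* is the proportion
of permutations more extreme than the observed value (an empirical
permutation p-value, named as in the field). Group sizes must be equal — the
number of connected components depends on the number of points.

For clouds of thousands of *genes* (a topological analogue of co-expression
networks) the full Rips complex is infeasible; a lazy-witness filtration over
20 maxmin landmarks (configurable) stands in, degenerating exactly to Rips
when every point is a landmark.

A parallel, non-topological track computes each case sample's Mahalanobis
distance from the control centroid (pseudoinverse covariance, since genes
usually outnumber samples) and tests the sum of squared distances (**SSMD**)
by the same relabeling scheme. Both statistics also scan GMT gene sets
against size-matched random sets.

## Worked example

```r
library(topohet)

ds <- generate_dataset(synth_config(n_genes = 60, n_per_group = 15,
                                    heterogeneity = 3, seed = 11))
ds
#> synthetic expression dataset: 60 genes x 30 samples (15 per group)
#>   heterogeneity 3.00 (all genes), 5 modules, seed 11

test <- label_permutation_test(ds$expression, ds$metadata,
                               group_statistic("SDT0", "sample"),
                               n_perm = 999, seed = 5)
test
#> label-permutation test of D_SDT (sample level, two-sided)
#>   D = case - control = 4.99592
#>   permutation FDR (as defined in the source analysis) = 0  [999 permutations, seed 5]

case <- split_by_group(ds$expression, ds$metadata)$case
summarize_diagram(rips_persistence(pearson_dissimilarity(case, "samples"),
                                   max_dim = 2))
#> diagram summary (sums over finite cycles)
#>  dimension        SL      SBT      SDT n_finite n_essential
#>          0 9.2528795 0.000000 9.252880       14           1
#>          1 0.4343387 5.123626 5.557964        7           0
#>          2 0.0000000 0.000000 0.000000        0           0
#> Euler characteristic (dims 0-2): chi = 8.81854
```

The case group's residual dispersion is tripled by construction, its 15
samples merge late (SDT₀ ≈ 9.25 vs ≈ 4 for controls), and none of the 999
random relabelings produce as extreme a difference — the heterogeneity is
detected. The seven dimension-1 cycles are transient (`SL₁` ≈ 0.43), so χ
stays close to SDT₀, as is typical for these clouds.

File-based pipelines (`run_analysis()`) and a CLI wrapper
(`inst/scripts/topohet-cli.R`, subcommands `simulate`, `sample-topology`,
`gene-topology`, `geneset-topology`, `mahalanobis`, `geneset-mahalanobis`,
`plot`) cover the same functionality end to end with JSON/TSV reports.

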