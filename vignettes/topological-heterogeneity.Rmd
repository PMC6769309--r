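---
title: "Quantifying transcriptome heterogeneity with persistent homology"
author: "topohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptome heterogeneity with persistent homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(topohet)
```

## The question and the model

Clinically heterogeneous disorders pose a question that differential
expression does not answer: are the *patients themselves* more dissimilar to
one another, at the level of the whole transcriptome, than controls are?
`topohet` answers it geometrically. Each group's samples form a point cloud —
one point per sample, with dissimilarity `1 - r` (`r` = Pearson correlation
of the two samples' expression profiles across all genes). The shape of that
cloud across scales is summarized by persistent homology, and group
differences in the summaries are tested by permuting group labels.

For a scale parameter `eps` growing from 0, the Vietoris–Rips complex
connects every pair of points within `eps` (and fills in triangles,
tetrahedra, … as soon as all their edges are present). Tracking homology with
Z/2 coefficients across this filtration records, for every topological cycle
(connected component, loop, void), the scale at which it is born and the
scale at which it dies. The filtration is truncated at `eps_max`, the largest
pairwise dissimilarity; classes still alive there are *essential*.

Three diagram summaries drive the analysis:

* `SDT_k` / `SBT_k` / `SL_k`: sums of death times, birth times, and lengths
  (`death - birth`) of the finite dimension-`k` cycles. Components are all
  born at 0, so `SL_0 = SDT_0`.
* `SDT_0` is the heterogeneity measure: points of a dispersed cloud merge
  late, so their components accumulate large death times. It equals the total
  weight of the minimum spanning tree of the cloud — which is also how the
  package computes it exactly in `zero_dim_persistence()` (union-find over
  edges sorted by weight), bypassing the full reduction.
* The Euler characteristic `chi = SL_0 - SL_1 + SL_2`, always over dimensions
  0–2 even when dimension 3 is computed (higher cycles are rare and
  transient in expression clouds; the dimension-3 sums are still reported).

Essential classes are excluded from all sums: a connected cloud always has
exactly one, identical in expectation for both groups, and any finite stand-in
for its "infinite" death would be arbitrary. Zero-length pairs
(`death == birth`) are dropped from diagrams — they contribute nothing to any
sum — while an internal conservation check (finite + essential dimension-0
classes = number of points) runs before dropping.

Inference: `D = invariant(group 1) - invariant(group 2)` (group labels in
sort order), compared with the same statistic under random equal-split
re-partitions of the pooled samples. The reported `fdr` is the proportion of
permutation values more extreme than the observed one — operationally an
empirical permutation p-value; the name follows the field's usage for this
design. "More extreme" defaults to two-sided (`|null| >= |observed|`), which
is symmetric under group swap; `sided = "greater"` restores the one-sided
variant.

## Worked example

```{r example}
ds <- generate_dataset(synth_config(n_genes = 60, n_per_group = 15,
                                    heterogeneity = 3, seed = 11))
test <- label_permutation_test(ds$expression, ds$metadata,
                               group_statistic("SDT0", "sample"),
                               n_perm = 999, seed = 5)
print(test)
```

## Gene-level clouds and the lazy-witness filtration

Dually, the genes of one group form a cloud (one point per gene,
`1 - r` across that group's samples) — a topological analogue of a
co-expression network. Thousands of points make the full Rips complex
infeasible, so `lazy_witness_persistence()` builds the filtration on a small
landmark subset (default 20, selected by the deterministic maxmin rule;
uniform random selection is available). An edge between landmarks `a` and `b`
enters at the smallest `t` such that some witness point `w` satisfies
`max(d(a, w), d(b, w)) <= t + m(w)`, where `m(w)` is `w`'s dissimilarity to
its `nu`-th nearest landmark (`nu = 1` default); higher simplices fill in
when their edges are present (flag rule), and reduction proceeds exactly as
in the full path.

**Witness convention.** In this package the witnesses for an edge are the
non-landmark points plus the edge's own endpoints; other landmarks do not
witness. This makes the construction degenerate *exactly* to Vietoris–Rips
when every point is a landmark and `nu = 1` (each edge is then witnessed by
its endpoints at precisely `d(a, b)`), which the test suite uses as the
correctness anchor. Under the textbook convention, where every point
witnesses every edge, a third landmark lying "between" two others can create
their edge early even with all points as landmarks, and no such exact anchor
exists. With sparse landmarks — the regime the construction exists for — the
two conventions all but coincide, since nearly all points are non-landmarks.

## The Mahalanobis track

As an independent, non-topological dispersion statistic, the package fits the
control samples' per-gene mean and sample covariance (denominator `n - 1`)
and computes each case sample's Mahalanobis distance
`MD = sqrt((x - mean)' pinv(Sigma) (x - mean))`. With more genes than
samples the covariance is singular by construction, so the Moore–Penrose
pseudoinverse is used throughout (singular values below
`machine epsilon * max(dim)` times the largest are treated as zero; the
cutoff is exposed as `rank_tolerance`). The test statistic is the sum of
squared case MDs (SSMD). Its permutation null *refits* the covariance on
each permuted control half — the only choice under which the permuted
statistic is computed the same way as the observed one. SSMD is a
non-negative dispersion measure asking specifically whether cases are *more*
dispersed, so its extremeness rule is one-sided (`null >= observed`).

## Gene-set scans

Both statistics restrict to gene sets (GMT input). Sets keep only genes
present in the matrix and must retain at least half of their members
(`filter_genesets()`); after intersection a topology scan needs at least 3
genes (fewer coordinates make correlation degenerate) and an SSMD scan at
least 2 — smaller sets are skipped with a warning rather than aborting a
collection-wide scan. The null for a set is not label permutation but
`n_random` (default 100) random gene sets of the same size drawn uniformly
from the expressed universe; draws do not exclude the tested set's genes (the
tested set is a vanishing fraction of the universe, and unrestricted draws
keep the null exchangeable). No correction across sets is applied beyond the
per-set resampling — the scan reports how many sets were tested so users can
apply their own.

## The synthetic generator

`generate_dataset()` stands in for case/control cohort data. Genes get
baselines `N(8, 1)` on the log2 scale and are assigned round-robin to
`n_modules` co-expression modules; each sample draws independent module
factors `N(0, 1)` entering with loading `module_strength`; residual noise is
`N(0, noise_sd)`, and the *case* group's residual scale is multiplied by
`heterogeneity >= 1` — either transcriptome-wide or, in restricted mode, on a
`floor(affected_fraction * n_genes)` gene subset. Heterogeneity is modeled as
inflated residual scale rather than mean shifts deliberately: it enlarges
within-group inter-sample distances (exactly what `SDT_0` measures) while
keeping group means equal, so differential-expression-like signals cannot
confound the topology. At `heterogeneity = 1` the groups follow the identical
law, giving exact exchangeability for calibration checks.

Defaults (`n_genes = 100`, `n_per_group = 15`, `n_modules = 5`,
`module_strength = 0.7`, `noise_sd = 0.7`) put within-group correlations
around 0.5 — a plausible regime for normalized tissue transcriptomes at
cohort scale, and small enough that thousands of permutation analyses run on
one CPU. What the generator does *not* emulate: count noise and library-size
effects (inputs are assumed already normalized to log2 scale), batch
structure, outlier samples, and heavy-tailed expression — so passing
calibration and power checks here demonstrates correctness of the machinery
and sensitivity under the stated model, not performance on raw sequencing
data.

## Numerical and design choices

* **Determinism.** One master seed; every randomized stage (each permutation,
  each random gene-set draw, each landmark selection) derives its own
  sub-seed from (seed, stage label, index), so any sub-analysis is
  reproducible in isolation and identical configs give byte-identical
  reports (wall clock aside).
* **Ordering ties.** Simplices are ordered by
  `(eps, dimension, lexicographic vertices)`. Tied dissimilarities are
  common; any valid order yields the same diagram, but the fixed order makes
  runs bit-reproducible.
* **Dissimilarity hygiene.** `1 - cor()` values are clamped to `[0, 2]`, the
  diagonal forced to exactly 0, and symmetry enforced. Constant
  (zero-variance) vectors are an error naming the offender; the explicit
  `drop_constant_genes()` pre-filter removes constant genes *before* group
  splitting so both groups keep the same gene universe.
* **Equal group sizes are enforced**, not warned about: the number of
  connected components depends on the number of points, so dimension-0
  invariants are only comparable between equal-sized clouds.
* **Dimension caps.** Sample-level analyses default to `max_dim = 2`,
  gene-level to 3 — matching where cycles actually occur in expression
  clouds; both configurable. A simplex-count ceiling (default `1e7`) guards
  the full enumeration and points to the lazy-witness path.
* **Quadratic forms** in the MD are clipped at zero before the square root
  to guard `-1e-18`-scale artifacts; SSMD additivity
  (`sum(md^2) == ssmd_observed`) is asserted to `1e-12` in tests.
* **Problem sizes.** The test suite and the acceptance script exercise the
  pipeline at 60–200 genes and 15 samples per group with 99–999
  permutations, and verify the persistence core against an independent
  dense Z/2 elimination oracle on hundreds of small random matrices and
  against minimum-spanning-tree weights up to 60 points — sizes chosen so
  that the full double-checked battery runs in minutes while every code path
  (full reduction, union-find, lazy witness, both scans) is exercised at
  realistic correlation structure.

## Known limitations

* Landmark choice and `nu` are not standardized across implementations;
  results at gene level depend (mildly) on them, so reports echo both.
* The permutation "FDR" is a single-test empirical p-value; scanning many
  gene sets still requires the user's own multiplicity control.
* `SDT_0` detects dispersion differences, not their direction of cause;
  mean-shift signals are deliberately invisible to it.
* The transcriptome-wide *gene-level* Mahalanobis analysis (one point per
  gene) is out of scope for cost reasons; the MD track operates at sample
  level and on gene sets.
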