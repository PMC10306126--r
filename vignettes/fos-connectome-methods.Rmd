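---
title: "Methods: Fos coactivation networks, modules, hubs and the expression screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fos coactivation networks, modules, hubs and the expression screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FosConnectome)
```

## The model

The raw signal is a region × subject table of Fos⁺ cell counts from two
groups of animals (control and treatment). Because Fos accumulates over
roughly 1–2 h of neuronal activation, across-subject covariation of
regional counts is read as functional coupling. The analysis makes three
assumptions worth keeping in view:

* **Log-scale linearity.** Counts span orders of magnitude, so all
  correlation is done on `log10(x + 1)`. The +1 offset keeps zero counts
  defined and maps them to exactly 0; for counts above ~100 it is
  negligible.
* **Across-subject Pearson correlation is meaningful at small n.** The
  study design this pipeline targets has 4–5 animals per group. With n = 4
  or 5 subjects, individual correlations are extremely noisy; the analyses
  that are robust at this scale are aggregate ones (edge counts, module
  counts, mean correlations over pair sets), and the per-group correlation
  step warns when a group has fewer than 4 subjects.
* **Binary connectivity above a fixed threshold.** A functional connection
  is a region pair with r strictly greater than the threshold (default
  0.75). Everything graph-theoretic (degree, betweenness, participation,
  hubs) treats the network as undirected and unweighted; reported edge
  counts are cardinalities of that binary edge set.

## Pipeline stages and their parameters

| Parameter | Default | Meaning |
|---|---|---|
| `correlationThreshold` | 0.75 | strict lower bound on r for an edge; in (0, 1], where 1 gives the empty graph |
| `linkageMethod` | `"complete"` | agglomeration for `hclust()` |
| `cutFraction` | 0.5 | dendrogram cut at this fraction of the maximum merge height |
| `hubTopK` | 20 | depth of the degree/betweenness/participation top lists |
| `fdrLevel` | 0.05 | Benjamini–Hochberg level of the gene screen |
| `excludedRegions` | `"FRP"` | regions dropped from the screen (frontal pole: an expression-density outlier) |

**Modules.** Regions are represented by their full correlation row
(including the unit diagonal entry), so two regions are close when they
correlate similarly with the whole brain; row distances are Euclidean. The
dendrogram is cut at `cutFraction × max(merge height)` — "half-height" at
the default — and the subtrees below the cut are the modules, numbered in
dendrogram leaf order. Lowering the cut fraction can only refine the
partition, so the module count is monotone non-increasing in
`cutFraction` (tested). The linkage method is a genuinely open choice: the
module counts this family of analyses reports depend on it, which is why
it is pinned to a default (`complete`, the `hclust()` convention for this
literature) *and* exposed in the configuration; the acceptance test for
published module counts sweeps single/average/Ward as well and reports the
sweep rather than silently asserting one method.

**Centrality and hubs.** Degree and betweenness come from igraph;
betweenness is the raw geodesic-fraction score without the
`2/((n−1)(n−2))` normalisation, since only ranks enter hub calls.
Participation `P_i = 1 − Σ_s (κ_is/k_i)²` and the within-module degree
z-score are computed in-package against the half-height partition of the
same group's matrix — the only partition the pipeline defines. The z-score
uses the population (n-divisor) standard deviation of within-module
degrees, the canonical Guimerà–Amaral/Brain-Connectivity-Toolbox
convention; modules with constant within-degree (including singletons) get
z = 0, and isolated nodes get degree, betweenness and participation 0.
Hub rule: regions in both the top-k degree and top-k betweenness lists
(k = 20 by default); "connector hubs" are the top-k by participation.
Ties at the k-th value are all included so the hub set cannot depend on an
arbitrary sort order. No numeric participation cutoff is asserted —
top-k is a pinned convention, not a published rule.

**Cholinergic subsystems.** The long-range cholinergic regions are split
into a basal forebrain set {MA, NDB, SI} and a brainstem–thalamic set
{MS, PPN, MH, LH}. MS is kept in the brainstem–thalamic set for pair
enumeration even though functionally it sits between the two systems:
that placement is what yields the 3/6/12 within/within/between pair counts
(and the error df of 36 in the 2 × 3 ANOVA on 42 pair-level observations),
and it is configurable through the metadata `subsystem` column. The ANOVA
observations are the *pair-level* correlations, not the three category
means — with 21 pairs × 2 treatments the residual df is 42 − 6 = 36, which
is the only layout consistent with that df. Raw r values (no Fisher
transform) enter means and the ANOVA, mirroring how average-R analyses are
reported in this literature; `averageSubgroupR(..., fisher = TRUE)` offers
the z-scale average for those who want the statistical nicety. Sums of
squares are type II (robust to unbalanced layouts; identical to type I on
balanced ones), and Tukey HSD runs across all treatment × category cells
rather than within treatment — the more conservative reading when the
published choice is ambiguous.

**Expression screen.** The log-fold change is the difference of group
means on the log10(x+1) scale — equivalently log10 of the ratio of
geometric means of (count+1) — which is the only definition consistent
with the pipeline's normalisation. Replicate in-situ experiments for a
gene are each centred and scaled over the shared region set and then
averaged, giving one profile, one test and one q-value per gene (the
per-experiment alternative can be had by passing the experiments as
distinct "genes"). Per-gene p-values use the exact t transform
`t = r√((n−2)/(1−r²))` on n−2 df (cross-checked against `cor.test` in the
tests); q-values are Benjamini–Hochberg with the denominator restricted to
testable genes — a zero-variance profile has no p-value and is excluded
rather than counted. The realised |r| significance frontier (smallest |r|
among significant genes) is reported per run; it falls as m or the signal
fraction grows, which is the expected BH adaptivity.

## What the synthetic generators emulate — and what they do not

`generateCounts()` draws log10-scale region values from a multivariate
normal with a block correlation structure (`withinR` inside ground-truth
modules, `betweenR` between them), exponentiates, subtracts the +1 offset
and rounds to non-negative integers. The treatment group's correlation
target additionally receives `globalRBoost` on every off-diagonal entry
(capped at 0.999) — a global-synchrony knob that reproduces, in silico,
the qualitative withdrawal phenomenon: mean correlation rises and the
half-height module count falls. Infeasible targets (non-positive
semi-definite) are an error, never silently repaired, because hidden
eigenvalue clipping would change planted effect sizes. Counts are
log-normal rather than Poisson because the analysis operates on
log10(x+1): planted correlations then survive the normalisation
interpretably. Defaults mirror the study scale where one exists (4–5
subjects per group; `baseLogMean = 2`, i.e. ~100 cells per region, with
`logSd = 0.4` spanning roughly 10–1000).

`generateExpression()` plants signal genes as
`ρ·z(LFC) + √(1−ρ²)·noise` on a latent z scale, adds per-experiment noise,
and maps affinely onto the non-negative percentage-of-pixels scale
(clipping sits ~5 SD out, so it effectively never distorts the planted
correlation). Null genes are independent noise.

What passing synthetic tests does **not** show about real data: real Fos
counts have region-specific means and dispersions, spatially structured
(not block-constant) correlations, negative correlations that Fos reads
poorly (it is a weak marker of inhibition), and registration/segmentation
artifacts. Module recovery at ARI > 0.9 under a planted 3-block truth
validates the clustering machinery, not the claim that biological modules
are block-like.

## Numerical conventions and degenerate inputs

* Strict inequality at the threshold: r exactly equal to the threshold is
  not an edge.
* Zero-variance regions within a group are excluded (with a warning and a
  record in the result) before correlation — Pearson is undefined for
  them and NaN propagation is worse.
* A single region clusters into one module with cut height 0.
* An ANOVA with constant response returns F = 0 (not 0/0) for every
  effect; an effect with zero sum of squares likewise gets F = 0, p = 1.
* Mann–Whitney comparisons use the exact null distribution for small
  tie-free samples and the tie-corrected normal approximation otherwise
  (the `wilcox.test` rule); identical samples give U = n₁n₂/2, p = 1.
* Missing counts are rejected, not imputed: the upstream cell-counting
  pipelines emit complete tables, and imputation would silently change
  correlations. Rows that are entirely missing are dropped with a
  warning.
* All generators take an explicit seed and use one RNG stream per call;
  identical specs give byte-identical artifacts, which the stage
  manifests (md5 checksums) make auditable.

## Validation problem sizes

The test suite validates each operation against independent brute-force
oracles (path-enumeration betweenness, double-loop participation, literal
BH step-up, closed-form balanced ANOVA, exhaustive Mann–Whitney
enumeration) on ~10³ random instances of ≤ 15 nodes, and validates the
composed pipeline on planted-truth data: 3 blocks × 20 regions at
withinR = 0.9 / betweenR = 0.1 with 40 subjects per group for module
recovery (ARI > 0.9), and — for the screen — 20 replicates of 150 regions
with 2000 null + 200 signal genes at ρ = 0.4, checking mean empirical FDR
≤ 5% and power > 50%. The synchrony-boost effect on module counts is
checked over 20 seeds at 3 × 20 regions, withinR 0.6, betweenR 0.2, boost
0 vs 0.25, 12 subjects per group — sizes chosen once as a realistic
middle ground between the study's n and the stability needed for a mean
over seeds.

## Known limitations

* The published hub sets, edge counts and module counts can only be
  reproduced when the user supplies the study's count table (see README);
  the package ships the machinery and the synthetic validation, not the
  third-party data.
* Pearson-on-log-counts assumes roughly elliptical joint behaviour across
  subjects; at n = 4–5 a single animal can dominate any pair correlation.
* The screen correlates baseline expression with activation *change*;
  it identifies candidates, not mechanisms, and per-gene aggregation
  assumes replicate in-situ experiments measure the same spatial pattern
  up to affine rescaling.
* Community detection is deliberately limited to the half-height
  dendrogram cut; modularity-optimising alternatives (Louvain, Infomap)
  are out of scope because the analyses this package reproduces define
  modules by that cut alone.
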