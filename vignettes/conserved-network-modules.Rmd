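---
title: "Conserved network modules from time-series expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved network modules from time-series expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscnet)
```

## The model

`tscnet` targets processes that unfold gradually through ordered
phenotype stages — replicative senescence of fibroblasts or mesenchymal
stem cells, stepwise tumor progression — where the interesting machinery
is not a subnetwork that appears or disappears at one transition but one
whose *wiring stays constant while its expression context drifts*.

The pipeline has five stages:

1. **Normalization.** Quantile normalization forces every time-point
   column onto one reference distribution (per-rank means of the
   column-sorted matrix), so that no time point dominates scoring through
   a shifted intensity distribution. It is optional (`normalize = FALSE`)
   for data already normalized upstream.
2. **Scoring.** The perturbation score
   `p_ij = e_ij - mean_k(e_ik)` measures each gene's deviation from its
   own temporal mean. Row sums are zero by construction: the score is
   relative within a gene, never across genes, so genes of very different
   absolute expression are comparable.
3. **Grouping and thresholding.** Scores of the raw time points inside a
   phenotype stage are averaged. All grouped scores (genes × stages) are
   pooled, and a stage score is *selected* when it lies strictly outside
   `mu ± k * sigma` (sample sd, default `k = 1`). The normality behind
   the band is a working assumption justified by the pooled sample size,
   not a tested property; `k = 2` or `3` typically selects too few genes
   to build networks.
4. **Networks.** A stage network keeps every scaffold PPI with at least
   one selected endpoint; the common network is the exact set
   intersection of the stage edge sets. Edges are canonicalized
   (lexicographic endpoint order, sorted, deduplicated, no self-loops) so
   intersection is plain set algebra — no isomorphism or topology
   similarity is involved.
5. **ΔP and significance.** For stages *a*, *b*, ΔP is the mean of
   `|p_g(a) - p_g(b)|` over the common network's member genes, using
   grouped *pre-threshold* scores. The null pools the edges of all stage
   networks (set union), redraws per stage a uniform without-replacement
   edge set of the observed size, intersects, and recomputes ΔP; after
   `n_iter` draws both an empirical p-value and a one-sided
   normal-approximation p-value are reported, for each adjacent stage
   pair plus (first, last).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `k` (threshold) | 1 | pooled sds | bands at ±2σ, ±3σ empty out the networks |
| `n_iter` | 10,000 | draws | resolves empirical p down to ~1e-4; the normal tail covers smaller |
| `threshold_on` | grouped | — | the worked example thresholds the grouped value; pooling ungrouped scores is the documented alternative |
| `null` | pooled | — | random same-sized draws from pooled observed edges; `label_permute` is a coarse sensitivity check |
| `collapse` method | mean | — | probe-to-gene collapsing; unbiased and symmetric |

## Design decisions where the design was open

* **Threshold population.** The band is computed on grouped scores pooled
  over all genes × stages, matching the order of operations in the worked
  example (the grouped value −0.2 is compared against ±0.376). A flag
  allows pooling the ungrouped scores instead; with equal-sized stages
  the grouped pool has smaller variance, so the two choices select
  different gene counts and are not interchangeable.
* **Strict boundaries.** A score exactly equal to a threshold is *not*
  selected. With continuous data this is measure-zero; it is fixed for
  reproducibility.
* **ΔP members.** ΔP averages over *all* nodes of the common network,
  including passive endpoints that were never individually selected.
  The alternative (selected genes only) cannot be distinguished from the
  source material; this choice keeps the statistic a function of the
  common network alone and is flagged in the report via `n_members`.
* **Empty random intersections** contribute ΔP = 0 to the null rather
  than being discarded — discarding would inflate the null mean and make
  the test conservative in a data-dependent way. The count of empty
  intersections is always reported so users can judge.
* **The `label_permute` null.** Permuting the stage labels of the
  observed edge sets is a no-op (intersection is order-invariant), so the
  alternative null permutes the stage labels of the *score columns*
  before recomputing ΔP on the observed common network. Its support is
  limited to the number of stage permutations; it is a sensitivity check,
  not a replacement for the pooled null.
* **Sample sd** (n−1) everywhere, so results are reproducible
  bit-for-bit against the documented formula.

## Numerical and degenerate-input behavior

* Quantile normalization handles ties by assigning the **mean of the
  reference values at the tied ranks** (group mean). Note this differs
  from fractional-rank interpolation (as in
  `limma::normalizeQuantiles(ties = TRUE)`) for ties of width > 2.
  Exact idempotence and exact cross-column multiset equality hold on
  tie-free data; tie-averaging collapses values, so on tied data both
  hold only approximately. The test suite checks equality against limma
  on tie-free matrices and the group-mean rule by hand-computed values.
* A single-time-point matrix is rejected (scores identically zero);
  an all-equal score matrix is rejected at thresholding (σ = 0) with a
  pointer to supplying a manual band.
* An empty common network is legal for extraction but aborts ΔP and the
  significance test with an explanatory report entry.
* The empirical p-value uses the add-one formula and is never 0; when
  the null sd is 0 (e.g., stage networks all equal to the pool) the
  parametric p is reported as undefined rather than faked.
* All randomness flows through R's global RNG; every entry point takes a
  `seed`, which is logged in results, and a fixed seed makes the entire
  run byte-reproducible.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` builds the stated world the package is tested in:
per-gene baselines from one common distribution (so normalization is
near-neutral by design and scoring behavior is isolated), i.i.d.
Gaussian noise per time point, and a planted module whose genes drift
*linearly* from −amplitude to +amplitude across time points, half upward
and half downward — the two opposed monotone profiles that a conserved,
context-shifting module produces. The scaffold is `module_edges` random
pairs inside the module plus `scaffold_edges` random background pairs.

Defaults describe a 500-gene, 8-time-point (4 stages × 2) experiment on
a log2-like scale: noise sd 0.2, amplitude 1 (a two-fold peak drift;
amplitude/noise = 5), module 10 genes / 12 edges, and 1000 background
edges (mean degree 4 — the density scale of a high-confidence PPI set
restricted to expressed genes). These were fixed a priori and are not
tuned to test outcomes.

Not emulated: array-platform effects, probe redundancy (except through
`collapse_duplicate_genes`), realistic PPI degree distributions
(hubs/scale-free structure), correlated noise between genes, or
non-monotone drift shapes.

## What a green — or red — test establishes

The unit and property suite establishes that every operation implements
its stated formula exactly (worked-example values, brute-force
intersection oracle, sampling-uniformity checks, linearity and
reproducibility properties). Two acceptance-level *method* properties,
however, fail in the stated world, and are deliberately left red rather
than weakened; both are findings about the method, not defects of the
implementation:

* **Null calibration.** Under data with no time structure (amplitude 0,
  columns i.i.d.), the empirical p-value is far from uniform: observed
  ΔP sits systematically above the resampling null's mean, and small
  p-values are heavily over-produced. The reason is selection bias: the
  observed common network's member genes earned their membership by
  having extreme scores at the tested stages, whereas a random same-sized
  draw from the pooled edges includes unselected passive endpoints with
  small score differences. The pooled-edge null therefore answers "is
  this ΔP large for a *random* set of observed edges?", not "would a
  dataset without time structure produce this ΔP?" — p-values from it
  should be read as descriptive enrichment scores, not calibrated
  frequentist error rates.
* **Edge-level recovery precision.** With a strongly drifting planted
  module, recall of planted edges in the common network is high (the
  module genes clear the threshold at every stage), but precision is
  bounded well below 1: every background scaffold edge *incident* to a
  module gene also satisfies the at-least-one-perturbed-endpoint rule at
  every stage and is conserved. The expected number of such halo edges is
  `scaffold_edges × P(pair touches the module)`, which exceeds the
  planted edge count for any realistic background density. The common
  network should be read as the module *plus its PPI neighborhood*; a
  both-endpoints-selected variant would change this trade-off but is a
  different method.

## Known limitations

* Gene identifiers are opaque strings; no probe/symbol mapping services.
* The significance test performs no multiple-testing correction across
  stage pairs.
* The normal-approximation p-value inherits the calibration caveat above
  *and* a normality assumption on the null; treat very small values as
  order-of-magnitude statements.
* GraphML export relies on igraph; per-node score attributes are written
  only for genes present in the score matrix.
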