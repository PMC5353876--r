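# tscnet

Identifies a **structurally conserved, context-shifting network module**
from time-series gene expression integrated with protein–protein
interactions (PPIs).

Most time-series network analyses ask which parts of a network *change*
topology over time. `tscnet` asks the opposite question: which
interactions persist at **every** phenotype stage while the expression
context of their genes drifts — the signature of a module that actively
tracks a gradual phenotypic transition such as replicative senescence or
tumor progression, rather than switching on or off at one step.

## Method

For a gene *i* with expression *e<sub>ij</sub>* at time point *j* out of
*M*, the **perturbation score** is the deviation from the gene's own
temporal mean:

> p(gene<sub>ij</sub>) = e<sub>ij</sub> − (1/M) Σ<sub>k</sub> e<sub>ik</sub>

after quantile normalization of the columns. Adjacent time points that
share a phenotype are grouped into **stages**, and the per-stage score is
the mean of the raw scores. Pooling all grouped scores, a gene is called
*perturbed* at a stage when its score falls strictly outside
μ ± kσ (default k = 1; sample sd). Each stage's **network** is every
scaffold PPI with at least one perturbed endpoint, and the **common
network** is the exact set intersection of the stage edge sets.

The context shift of the common network between stages *a* and *b* is

> ΔP(a, b) = mean over member genes g of | p<sub>g</sub>(a) − p<sub>g</sub>(b) |

using grouped, pre-threshold scores over all common-network nodes.
Its significance is assessed against a resampling null: pool the edges of
all stage networks, draw per stage a random same-sized edge set (uniform,
without replacement), intersect, recompute ΔP; repeat (default 10,000
iterations). Both the empirical p-value `(1 + #{null ≥ obs}) / (N + 1)`
and a one-sided normal-approximation p-value from the null mean and sd
are reported, for every adjacent stage pair plus the (first, last) pair.

## Worked example

```r
library(tscnet)
sim <- simulate_dataset(n_genes = 200, scaffold_edges = 400, seed = 42)
res <- run_pipeline(sim$expression, sim$interactions, sim$grouping,
                    n_iter = 1000, seed = 42)
print(res)
```

```
Conserved-module pipeline run
  genes: 200  scaffold edges: 412  stages: 4
  threshold band: (-0.1866, 0.1866)  [k = 1]
  stage1: 41 perturbed genes, 131 nodes / 166 edges (40.291%)
  stage2: 36 perturbed genes, 120 nodes / 145 edges (35.194%)
  stage3: 32 perturbed genes, 127 nodes / 150 edges (36.408%)
  stage4: 37 perturbed genes, 120 nodes / 135 edges (32.767%)
  common network: 51 nodes / 51 edges (12.379%)
  stage1 vs stage2: delta-P 0.3001, null 0.2348 +/- 0.02887, empirical p 0.02198, normal p 0.01194
  stage2 vs stage3: delta-P 0.26, null 0.2273 +/- 0.02743, empirical p 0.1109, normal p 0.1169
  stage3 vs stage4: delta-P 0.2354, null 0.2013 +/- 0.02429, empirical p 0.08691, normal p 0.07979
  stage1 vs stage4: delta-P 0.4657, null 0.345 +/- 0.07097, empirical p 0.04296, normal p 0.04454
```

Reading it: the simulated dataset plants a 10-gene module whose scores
drift monotonically from one extreme to the other across the four
stages. Each stage selects ~35% of scaffold edges; only 12% survive the
four-way intersection. ΔP is largest — and smallest in p — for the
(first, last) comparison, where the planted drift is maximal; 10 of the
12 planted edges sit in the recovered common network (the other common
edges are the module's PPI neighbors, conserved because one endpoint is
a module gene).

The per-run artifacts (score tables, per-stage networks, the common
network as edge TSV and GraphML with per-stage node scores, score
profiles of the module genes, and a key/value report) are written when
`output_dir` is given.

## Command line

```sh
Rscript inst/cli/tscnet.R simulate --out sim --seed 1
Rscript inst/cli/tscnet.R run --expression sim/expression.tsv \
    --interactions sim/interactions.tsv --grouping sim/grouping.json \
    --out results --seed 1 --iterations 10000
```

Subcommands: `run`, `simulate`, `normalize`, `score`, `networks`,
`common`, `test`; all accept `--seed`, `--threshold-k`, `--iterations`,
`--no-normalize`, `--gene-list`, `--null {pooled|label-permute}`.

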