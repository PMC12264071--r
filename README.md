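# pathfuse

Decision-level fusion of histology cell graphs and multiomics for tumor
prognosis, implemented natively in R.

## What problem this solves

Survival risk after a cancer diagnosis is written in two places at once: in
tissue morphology — the size, shape and spatial arrangement of nuclei in
H&E slides — and in molecular state — transcription, somatic mutation, DNA
methylation. Models built on either alone discard the other half of the
signal. `pathfuse` is for computational-oncology researchers who want a
complete, reproducible implementation of a decision-level fusion pipeline:
each modality is encoded close to the prediction head, and the two
embeddings are fused by an outer tensor product before a Cox survival
layer.

The package contains the full method and everything needed to exercise it
without external data: omics filtering, tile QC and nuclei featurization,
spatial-graph construction, both neural branches (hand-implemented in base
R matrix code with analytic backpropagation), tensor fusion, two-stage
training, survival metrics, and a synthetic cohort generator with known
ground-truth risk.

## The model

**Histology branch.** Each tile's segmented nuclei become nodes of a
spatial graph: 17 morphological features plus a 1024-d patch embedding per
nucleus (1041 attributes), edges from symmetrized 5-nearest-neighbor
search on centroids. Three GraphSAGE convolutions

    h'_v = ReLU( W [ h_v ; mean_{u in N(v)} h_u ] )

are followed by a SAGPool layer (self-attention scores from a 1-d
GraphSAGE map; top half of nodes kept, scaled by tanh of score). Mean
readouts of the three layers, concatenated and linearly mapped, give the
graph embedding `z_g` (128-d); a patient is the mean of their tile
embeddings.

**Omics branch.** Expression (differentially filtered tumor vs normal:
|log2 FC| > 1 and BH-FDR < 0.05), mutation (sites mutated in > 80% of
samples), and methylation (M-values, `log2(b/(1-b))`) each pass through
their own MLP to a shared 32-d space and are summed: `z_o`.

**Tensor fusion and survival head.** With a 1 prepended to each embedding,

    Z = (1, z_g) (1, z_o)^T          # (128+1) x (32+1) = 4257 entries
    theta = <W, Z> + b               # scalar log-hazard, d_h = 1

so Z carries both unimodal embeddings (first row / column) and all
multiplicative interactions. Training minimizes the negative Cox partial
log-likelihood with Breslow ties,

    loss = - sum_{i : event} [ theta_i - log sum_{j : t_j >= t_i} exp(theta_j) ],

by SGD (batch 20, lr 0.01 decayed x0.1 every 10 epochs at reference
settings). Training is two-stage: both branches are trained alone first,
then the fusion head starts from the transplanted single-modal head
weights and refines the interaction terms. Models are compared by
Harrell's concordance index, Kaplan-Meier curves with log-rank tests on
median-split risk groups, a fixed-horizon AUC, and a clinical Cox
baseline.

## Worked example

A complete synthetic experiment — generate a 120-patient cohort whose risk
is split half/half between morphology and omics, cross-validate all three
models on shared folds, and compare pooled out-of-fold concordance:

```r
library(pathfuse)
res <- run_fusion_benchmark(seed = 1)
round(res$c_index, 3)
#>  graph  omics fusion
#>  0.622  0.660  0.704
```

The graph-only and omics-only models each see only their half of the
latent risk and land in the low-to-mid 0.6s; the fusion model, combining
both, reaches 0.704 here (0.64-0.75 across seeds, above both single-modal
models in 10 of 10 seeded replicates). For reference, the true latent risk
scores C ~ 0.75 on cohorts of this design, so fusion recovers most of the
achievable signal. On a null cohort (`run_fusion_benchmark(seed = 1,
beta = 0)`) all three models stay near 0.5 (0.51, 0.53, 0.51).

Single pieces are just as usable on their own:

```r
tiles <- make_tiles(3, risk = 0.5, seed = 7)      # synthetic H&E-like tiles
tile_qc(tiles[[1]])                               # background / density QC
g <- build_graph(tiles[[1]], k = 5, embed_dim = 1024, seed = 1)
ncol(g$node_attrs)                                # 1041 = 17 + 1024
cox_pll_loss(c(0, 0), times = c(1, 2), events = c(1, 1))  # log(2)
```

A YAML-configurable pipeline (`run_pipeline()`) chains simulate, omics
prep, training and evaluation, writing metrics JSON, KM tables,
checkpoints and an MD5 manifest; `inst/cli/pathfuse.R` is a thin
command-line wrapper with `simulate`, `prep-omics`, `graph` and
`pipeline` subcommands.

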