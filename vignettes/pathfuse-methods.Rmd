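---
title: "Decision-level fusion of nuclei graphs and multiomics for survival prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-level fusion of nuclei graphs and multiomics for survival prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumor prognosis depends jointly on tissue architecture — how nuclei are
shaped and arranged in the microenvironment — and on molecular state:
transcription, somatic mutation, DNA methylation. `pathfuse` implements a
decision-level multimodal fusion framework for predicting patient survival
risk from both: histology enters as node-attributed spatial graphs of
segmented nuclei, omics as three filtered feature matrices, and the two
modality embeddings are combined by an outer tensor product feeding a
Cox-style hazard head. Everything is trained with the Cox partial
log-likelihood, so the model learns relative hazard orderings under right
censoring.

The package covers the full path: omics preprocessing filters, tile quality
control and nuclei featurization, graph construction, both branch encoders,
tensor fusion, training, evaluation metrics, and a synthetic cohort
generator so that the whole method runs and is tested end-to-end with no
external data.

## The histology branch

Nuclei instance segmentation is upstream of this package: a tile is an RGB
image plus an instance label mask. For each nucleus we extract 17
morphological features — area, minor/major axis lengths of the
second-moment ellipse, maximum inscribed-circle radius (computed from the
distance to the region's complement), per-channel and gray mean / range /
standard deviation, and the centroid distance to the nearest nucleus — and
a 1024-dimensional patch embedding of the 64 x 64 region centered on the
nucleus. The default embedding is a seeded, fixed Gaussian random
projection of the flattened zero-mean patch: it is deterministic, preserves
the interface dimensionality, and can be swapped for any learned encoder
via the `encoder` argument of `build_graph()`. Nuclei are connected to
their 5 nearest neighbors (Euclidean, deterministic tie-break by distance
then index), symmetrized to an undirected graph.

The encoder is a three-layer GraphSAGE network: each layer computes
`h'_v = ReLU(W [h_v ; mean of neighbor h])`, so a node combines its own
state with the mean of its neighborhood. After the third convolution a
single SAGPool layer scores nodes with a one-dimensional GraphSAGE map,
keeps the top `ceiling(0.5 N)` and scales kept attributes by
`tanh(score)`. Mean readouts of the three layers are concatenated and a
fully connected layer maps them to the 128-dimensional graph embedding
`z_g`. A patient's embedding is the mean over their tile embeddings.

Two places in this architecture were genuinely open and are configurable:

* **Readout of the third layer.** Reading all three layer readouts before
  pooling would leave the pooling layer outside every gradient path — the
  scores would never train and pooling would not affect the embedding. The
  default therefore takes the third readout *after* pooling (mean over the
  kept, tanh-scaled nodes); `gcn_config(readout3 = "pre_pool")` restores
  the alternative.
* **Pool ratio** defaults to 0.5 and is a config value.

## The omics branch

Expression, mutation and methylation are first reduced to informative
features. Expression uses a tumor-versus-normal differential filter: keep
features with `|log2 FC| >` a threshold (default 1; fold change on group
means with a pseudocount of 1, the standard guard against zero means) *and*
Benjamini-Hochberg adjusted p below a threshold (default 0.05). The test is
a self-contained Welch t-test on `log2(x + 1)` values — a deliberate,
documented divergence from count-model DE packages, keeping the module
dependency-free while preserving the interface; thresholds are config
values, never hard-coded, since reasonable analyses vary them. Mutation
sites are kept when mutated in *strictly more than* 80% of samples (the
boundary is unit-tested). Methylation beta-values are mapped to M-values
`log2(b/(1-b))` with clipping at `epsilon = 1e-6` so boundary betas stay
finite. Samples are intersected across the three modalities in sorted
order.

Each modality then passes through its own MLP (ReLU hidden layers, linear
output) to a shared 32-dimensional embedding; the three outputs are summed
elementwise (mean offered) to give `z_o`. Hidden widths are unspecified by
the method and default to in-256-64-32; all sizes are config values.

## Tensor fusion and the survival head

The fused representation is the outer product of the unit-padded
embeddings:

    Z = (1, z_g) (1, z_o)^T,   dim (d1+1) x (d2+1) = 129 x 33 = 4257

`Z[1,1] = 1` carries the constant, the first row and column carry each
unimodal embedding unchanged, and the interior block all multiplicative
pairwise interactions. Flattening is row-major, fixed so checkpoints are
portable. The hazard head maps Z to a scalar log-hazard
`theta = <W, Z> + b` with output dimension 1 — the fusion equation is a
single linear map of the fused tensor, and that linear head is the
default; a Cox-nnet-style tanh hidden layer is available via
`use_hidden = TRUE` for a nonlinear head.

Because the first row and column of Z are exactly `(1, z_o)` and
`(1, z_g)`, the pretrained single-modal head weights can be transplanted
into those entries of W at initialization (rescaled for the feature
standardization). The fusion model then *starts* at the additive
combination of the two pretrained predictors and SGD refines the
interaction entries — the package's concrete reading of initializing the
fusion network from single-modal weights rather than training it
end-to-end. Accordingly the fusion stage is a gentle refinement: at
fixture-scale cohorts (about a hundred training patients against 153 fused
features) aggressive SGD on the interaction entries only overfits, so the
desk-scale default refines at `lr0_fusion = 0.001` and the optional ridge
shrinks toward the transplanted solution rather than toward zero.

Training minimizes the negative Cox partial log-likelihood

    loss = - sum over events i of [ theta_i - log sum_{j : t_j >= t_i} exp(theta_j) ]

with Breslow handling of ties (patients tied with i stay in the risk set,
matching the indicator `R_ij = 1 iff t_i <= t_j`). The printed form of this
cost in the source method sums `exp(theta_i)` inside the risk-set sum; the
implementation uses `exp(theta_j)` over the risk set — the standard partial
likelihood that the cited Cox-nnet head also uses — and the loss is the
negative of the cost so that minimizing maximizes the likelihood. The
implementation is verified against a brute-force risk-set enumeration to
1e-10 and its analytic gradient against finite differences to 1e-5.

## Training regime

Stochastic gradient descent with batch size 20, initial learning rate 0.01
decreased tenfold every 10 epochs, weights initialized `N(0, 0.01^2)`, 50
epochs for the single-modal stages — all config values with these
defaults. Risk sets are computed within each minibatch (the only reading
consistent with batched training); the batch loss is normalized by the
number of events in the batch so the learning rate is insensitive to batch
composition, and batches without events are skipped. A small Cox-nnet-style
ridge penalty (`weight_decay = 1e-4`) applies to weight matrices only.

Training is two-stage: the graph and omics branches are trained from
scratch with linear Cox heads; the fusion stage then takes both pretrained
checkpoints, computes each patient's frozen embeddings, and trains the
fusion head on the fused tensors (default 20-25 epochs). Freezing the
branches is the package's reading of "initialize from single-modal weights
rather than training end-to-end": it keeps the fusion stage convex-ish,
cheap, and faithful to the two-stage description; end-to-end fine-tuning is
deliberately out of scope. Fused features (and node attributes, and the
omics design matrices) are z-scored with training-set statistics stored in
the checkpoint — a numerical necessity for SGD on raw pixel-scale
features.

All randomness flows from one master seed through named sub-streams
(`derive_seed`), so every fit, fold assignment and fixture is exactly
reproducible; two runs with the same configuration produce byte-identical
metrics.

## The synthetic cohort generator

The generator is the package's study fixture, not a convenience: its
defaults define the conditions under which the end-to-end claims are
tested.

* **Latent risk.** Each patient has a standard-normal risk split into
  independent morphology and omics components
  (`risk = sqrt(0.5) r_img + sqrt(0.5) r_om` by default), so each modality
  alone sees only part of the signal and fusion has something real to
  gain.
* **Tiles.** Nucleus counts are Poisson (default mean 25 per 160 px tile,
  a moderate density at desk scale); nuclei are rendered as
  hematoxylin-dark ellipses on eosin-pink tissue with per-pixel Gaussian
  noise. Mean nuclear area scales as `exp(area_effect * r_img)` and the
  axis ratio grows with risk — the signal lives exactly in features the 17
  extracted morphology values measure, so the implemented pipeline can in
  principle recover it.
* **Omics.** Log-normal expression, Bernoulli mutation, Beta methylation;
  a quarter of features per modality are causal, shifted on the natural
  parameter scale by `effect * r_om`. Causal expression features also
  carry a planted tumor-versus-normal log2 fold change of 2 for the
  differential filter to find.
* **Survival.** `t ~ Exponential(h0 exp(beta * risk))` with `h0 = 1/1000`
  per day and `beta = 1.2` — the proportional-hazards model the loss
  assumes, which is the point: the generator tests the estimator under its
  own assumptions. Independent exponential censoring is calibrated by
  root-finding so the expected censored fraction hits the target (default
  0.30). A Weibull-shaped alternative was considered and rejected for the
  default: exponential is the simplest generator consistent with the Cox
  model, and shape misspecification is not what these tests are about.

What the generator does *not* emulate: real H&E texture, stain variation,
segmentation errors, batch effects, probe structure, or non-proportional
hazards. Passing the end-to-end tests therefore shows the pipeline is
correctly wired and can learn planted multimodal signal under its model
assumptions — it says nothing about performance on real cohorts.

## Desk-scale problem sizes

The package's experiment sizes were chosen so that a full cross-validated
three-model comparison is a minutes-scale computation on a single CPU:
cohorts of 120 patients, 3 tiles of 160 px per patient, an 8-dimensional
patch embedding, GCN widths 24-16-16 to a 16-dimensional `z_g`, omics MLPs
32-16 to an 8-dimensional `z_o` (fused tensor 17 x 9 = 153), 5-fold
cross-validation with pooled out-of-fold scoring, 30 single-modal epochs
with `lr0 = 0.05` and `init_sd = 0.1`, and 25 fusion epochs at
`lr0 = 0.001`. The shapes and training regime are identical to
the full-size configuration; only widths and counts shrink. Two desk-scale
optimizer deviations deserve note, both found by examining convergence
(training-loss trajectories and held-out fit quality) at this scale: with
only a handful of minibatch updates per epoch the reference settings
(lr 0.01, init sd 0.01) move the randomly initialized branches too little
to converge, so the single-modal stages use larger values; and the fusion
stage, starting from transplanted single-modal weights, generalizes best
when refined gently (lr 0.001). Pooled out-of-fold Cox scores are centered
within each fold before pooling — per-model scores are identified only up
to an additive constant, and uncentered pooling leaks intercept drift into
cross-fold comparisons, visibly biasing the concordance even on null
cohorts. All of these are plain config values.

## Numerical and convention choices

* Gray value = `0.299 R + 0.587 G + 0.114 B`; background pixel = luminance
  above 220 (8-bit), configurable — the method names no threshold.
* "Moderate nuclei density" is operationalized as a count interval
  (default 10-2000 per tile), configurable.
* Inscribed-circle radius interprets the ambiguous "major inner circle"
  feature as the maximum inscribed circle via distance-to-complement, the
  only standard operator matching the words.
* Nearest-cell distance is centroid-to-centroid; a single-nucleus tile
  gets 0 with a warning (graph construction requires at least two nuclei
  regardless).
* C-index follows Harrell: score ties get half credit, pairs tied in time
  with two events are not comparable.
* Median stratification sends scores strictly above the median to the
  high-risk group; with all scores equal everyone is low-risk.
* The five-year horizon AUC excludes patients censored before the horizon
  (the simplest published convention); inverse-probability-of-censoring
  weighting would be the natural extension.
* Under a complete null the Benjamini-Hochberg step keeps (almost) no
  features — the filter controls the false-discovery *rate*; the null test
  asserts that control rather than a fixed false-positive count.
* Fold draws that leave a fold without events are redrawn with an offset
  seed and logged.

## Known limitations

The default patch encoder is a random projection, not a learned
representation; it preserves dimensionality and determinism but carries
little semantic content, so in the synthetic experiments the morphology
signal is learned essentially from the 17 handcrafted features. Tile
aggregation is a plain mean; attention over tiles is out of scope. The
fusion stage does not fine-tune the branches. Efron tie-handling,
time-varying covariates and IPCW metrics are not implemented.
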