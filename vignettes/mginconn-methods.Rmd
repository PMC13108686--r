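---
title: "Multi-modal GIN classification of functional connectomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal GIN classification of functional connectomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`mginconn`, the assumptions behind them, the parameters that matter, and
the design decisions taken where the method left genuine freedom. It
states no empirical results beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## From time series to brain graphs

Each subject contributes one ROI-mean BOLD time-series matrix (T
timepoints x N ROIs, atlas column order) per acquisition paradigm. The
construction chain per paradigm is:

1. **Pearson functional connectivity**: `r = cov(x_i, x_j) / (s_i s_j)`
   for every ROI pair; unit diagonal, symmetric.
2. **Absolute value, zero diagonal**: edge weights are `|r|`. The diagonal
   is zeroed because the GIN update carries the self term separately
   through its `(1 + eps)` factor; a self-loop would double-count it.
3. **Connection-profile node features**: node *v*'s feature vector is row
   *v* of the `|r|` matrix, keeping the complete pairwise-connectivity
   pattern at each node (the `degree` and `eigen` alternatives exist for
   the node-feature ablation).
4. **Box-Cox normalisation** of every feature column — fitted by profile
   maximum likelihood over lambda in [-2, 2] on *training subjects only*
   (all nodes of all training graphs stacked), then applied everywhere.
   `|r|` can be exactly zero, so a shift of `max(0, 1e-6 - min)` enforces
   positivity; 1e-6 is the smallest perturbation that preserves order
   without distorting the bulk of the distribution.
5. **Cosine edge attributes**: `S[i,j]` is the cosine similarity of the
   two nodes' connection profiles. The package also provides a `spatial`
   mode (`exp(-d/tau)` of the inter-centroid MNI distance, `tau` = 50 mm
   by default) because edge attributes based on feature similarity and on
   spatial proximity are both plausible readings of the construction;
   `cosine` is the default. Edge attributes are *not* consumed by the
   default model — the GIN aggregation uses `|r|` weights — but can be
   multiplied into the adjacency with `use_edge_attr = TRUE`.

Graphs are dense and weighted by default: using all connections without
pre-selecting features is the point of the approach. Top-k-per-node
sparsification (symmetrised by union) is available but opt-in.

## The classifier

Per modality, K GIN layers (default K = 2) update the node features:

    h_v^(k) = MLP^(k)( (1 + eps^(k)) h_v^(k-1) + sum_u A[v,u] h_u^(k-1) )

Design choices, and why:

- **Weighted aggregation.** The canonical GIN update sums unweighted
  neighbours, but on a dense `|r|` graph every node would aggregate every
  other node equally and the sum would carry almost no structure. The
  neighbour sum is therefore weighted by the adjacency (`A %*% H`); an
  unweighted mode binarises `A` for analyses on combinatorial graphs.
- **MLP shape.** Affine -> ReLU -> affine, hidden width = output width
  (`hidden_dim`). `eps` starts at 0 and is learnable.
- **Readout.** Per-layer node sums, concatenated across layers *including
  the raw input features* (the k = 0 term); a flag can exclude it. Sum
  pooling keeps the readout permutation-invariant and additive over
  disjoint graph unions, which the tests exploit.
- **Fusion.** The per-modality readouts are concatenated, passed through
  ReLU, an affine map to two logits, and a softmax — the most literal
  reading of "an activation merges the modality embeddings".
- **Loss.** Mean binary cross-entropy plus `weight_decay/2 * sum(W^2)`
  over the MLP and fusion weight matrices (biases and eps excluded).

The whole engine is plain R matrix algebra with hand-derived gradients;
training batches all subjects into one block-diagonal sparse adjacency so
an epoch is a handful of large matrix products. Analytic gradients are
verified against central finite differences in the test suite, and the
layer itself against a per-node loop oracle.

**Expressiveness.** With uniform node features and shared weights a GIN
cannot separate graphs that 1-WL colour refinement cannot separate. The
package ships `wl_refine`/`wl_distinguished` (injective hashing via a
canonical-string dictionary) as an oracle; tests confirm the classic blind
spot (C6 vs two disjoint C3 embed identically) and that WL-separable pairs
(P3 vs C3, and all non-isomorphic 5-node graphs) are separated by almost
every random initialisation.

## Training protocol

`train_config()` records the published protocol for a real 264-ROI cohort:
Adam, learning rate 1e-5, 3000 epochs, weight decay 0.2, hidden width 100,
80/10/10 stratified splits, 10 repeated experiments and 10-fold
cross-validation, accuracy/F1/AUC reported as mean +/- sample (ddof = 1)
standard deviation with paired t-tests between configurations.

Decisions worth recording:

- **Split sizes** follow the floor rule (`val = floor(0.1 n)`,
  `test = floor(0.1 n)`, train the remainder), stratified by the class
  label with largest-remainder allocation; n = 622 gives 498/62/62.
- **"Bootstrap" repeats** are repeated random re-splits (split, train,
  test per repeat), which is what the protocol describes; a true
  resampling-with-replacement mode exists behind `mode = "resample"`.
- **Checkpointing.** The best-validation-loss checkpoint (evaluated every
  `eval_every` epochs) is used for testing; final-epoch weights are also
  kept. K-fold runs use final weights (no inner validation split).
- **Leakage discipline.** Box-Cox fitting and checkpoint selection are
  separate operations taking explicit index sets; `run_experiment()`
  returns an audit of which indices each saw, and tests assert the test
  set is disjoint from both.
- **Degenerate paired t-tests** (zero-variance differences) return a
  degenerate flag rather than a fabricated p-value.

**Desk-scale settings.** The synthetic scenarios below are far cleaner
than real fMRI data, so `synthetic_train_config()` uses 150 epochs at
learning rate 1e-3, hidden width 32 and weight decay 1e-4 — enough for the
training loss to reach the 1e-3 early-stop tolerance on separable cohorts
within seconds on one CPU. These were fixed when the scenarios were
designed, from the convergence behaviour of the training loss, and are
deliberately not per-experiment tunables.

## Explainer

`explain_subject()` learns, per modality, a symmetric edge mask
(sigmoid of upper-triangle logits) and a per-feature mask, by plain
gradient descent (150 steps, learning rate 0.5) on

    prediction + 200 * mean(F) + 20 * mean(H_b(F))
               + 0 * population_size + 1000 * sum((A*M - A)^2)

where `H_b` is binary entropy, `M` the edge mask and `F` the feature mask.
The mutual-information objective of the underlying method is implemented
as its standard surrogate: cross-entropy of the model's prediction on the
masked graph against the model's own original prediction (the label
entropy term is constant).

Design decisions:

- **Two-pass prediction loss.** The edge mask is judged with the original
  features and the feature mask with the original edges. Jointly masking
  both lets the feature mask — which the strong size penalty drives toward
  zero — corrupt the gradients reaching the edge mask.
- **Sum, not mean, for the edge-deviation penalty.** A mean reduction
  divides the per-edge gradient by ~N^2/2, so on realistic atlas sizes the
  prescribed weights and step count would leave every mask at its 0.5
  initialisation. The summed form matches how reference implementations
  reduce size-type penalties and gives the term its intended strength at
  any N.
- **Plain gradient descent, not Adam.** A step size of 0.5 only makes
  sense for raw gradients, and sign-normalising optimisers erase the
  gradient-magnitude differences that make the final mask values a
  *ranking* of edges.
- **Deterministic start.** Mask logits start at exactly 0 (masks 0.5), so
  explanations are reproducible without any RNG.
- **Group masks and thresholds.** Subject masks are averaged within a
  (class, stage, modality) stratum *first*, then the top 5 % of unique
  pairs is taken (floor rule: 1735 edges for N = 264); cross-set "common"
  connections are intersections of the per-set top lists. Because the
  masks are multiplicative, a group that differs by *absence* of
  connectivity cannot be highlighted; recovery experiments therefore read
  the mean mask of the effect-carrying class, mirroring per-group
  explanation practice.

## Synthetic cohorts

`generate_cohort()` draws, per subject and paradigm, a Gaussian AR(1)
process whose stationary cross-sectional covariance is the group's target
correlation matrix: background correlation `base` everywhere, plus `delta`
on all pairs inside designated ROI blocks for group 1, in the block's
paradigms (eigenvalue clipping repairs borderline indefiniteness and
refuses specs whose repair moves any entry by more than 0.05). Ages are
drawn from the five-stage adolescence distribution (Pre 8-12, Early 12-14,
Middle 14-16, Late 16-18, Post 18-22, in the proportions of a 622-subject
developmental cohort) and staged with half-open intervals, the final one
closed — published stage tables share endpoints, and this is the unique
convention that partitions [8, 22].

The reference presets use N = 40 ROIs, T = 300 timepoints, 100 subjects
per group, background correlation 0.1 and AR coefficient 0.3:

- `shared_signal` — one 8-ROI block, delta 0.3, in both paradigms. At
  T = 300 the sampling noise of a correlation estimate is roughly 0.06, so
  the effect is strong and classification should approach ceiling.
- `complementary` — two disjoint 8-ROI blocks, one per paradigm, delta
  0.15 each: individually weak, jointly informative, the configuration in
  which modality fusion should beat either single paradigm.
- `weak` — the shared block at delta 0.15.
- `null` — no planted effect; accuracy should sit in the binomial chance
  band.

What the generator does *not* emulate: haemodynamic response functions,
scanner and motion artefacts, site effects, and the heavy-tailed,
spatially autocorrelated noise of real BOLD. Passing the recovery
experiments therefore demonstrates the correctness of the pipeline's
machinery on data satisfying its statistical assumptions — not performance
on real cohorts, whose effects are far weaker (real-data accuracies in
this literature sit near 0.8, not 1.0).

## Numerical choices and degenerate inputs

- Probabilities are clamped at 1e-12 before logs; softmax subtracts the
  row maximum.
- Box-Cox: constant feature columns get lambda = 1 with a warning;
  apply-time values below the training minimum are clamped to 1e-6 with a
  warning.
- Zero-norm rows in the cosine step get similarity 0 with a warning.
- AUC uses midranks, so ties count 1/2 exactly; single-class evaluation
  sets report AUC as missing.
- Accuracy thresholds at 0.5 with ties to class 0.
- Top-edge ties break lexicographically by (i, j) for determinism.
- Training aborts on non-finite losses, reporting the epoch and learning
  rate; the explainer does the same with its configuration echoed.
- All randomness (initialisation, splits, sampling) derives from explicit
  seeds; repeated runs are bitwise reproducible in serial execution.

## Problem sizes used in the shipped experiments

The test suite and acceptance script run the presets above (200 subjects,
40 ROIs, two paradigms), 5 repeats for the shared-signal recovery, 10 for
the null control and for each arm of the modality comparison, and explain
20 subjects (10 per class) for the recovery/fidelity experiment. These
sizes were chosen so the full validation cycle completes in minutes on a
single CPU while keeping every comparison's sampling error far from its
acceptance margin.

## Known limitations

- The GIN engine is CPU-only, full-batch, and written for clarity over
  speed; cohorts of a few hundred subjects at a few hundred ROIs are the
  intended scale.
- Mini-batching, attention/pooling variants and alternative explainers
  (gradient saliency, parameterised explainers) are out of scope.
- The explainer's multiplicative masks cannot express "this edge should be
  stronger"; see the group-mask note above.
- `Layer 1 Size 69696` in the published hyperparameter table equals 264^2
  and its role (flattened-input width vs layer width) is not recoverable
  from the text; the implementation keeps node features at width N and
  leaves the first MLP width configurable.
- Whether subjects contribute one FC matrix per scan or windowed matrices
  is left as one-per-scan-per-paradigm; dynamic connectivity is a
  non-goal.
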