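---
title: "Dual-branch deconvolution of bulk RNA-seq: model, simulator and subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch deconvolution of bulk RNA-seq: model, simulator and subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A bulk RNA-seq sample measures the summed transcription of a mixture of
cell types.  Writing the per-type expression profiles as the columns of a
genes-by-types matrix $G$ and the mixing weights as a proportion vector
$p$ on the simplex, the linear mixing model is

$$ G\,p = b, $$

with $b$ the observed bulk expression vector.  Classical deconvolution
estimates only $p$ against a fixed reference $G$.  `duodecon` predicts both
quantities per sample: the proportions **and** a sample-specific $G$,
which is what makes downstream per-patient, per-cell-type analyses (such
as the cell-state subtyping below) possible.

## The network

The model is a dual-branch feed-forward network:

* a **shared linear layer** maps the input gene vector (log2 CPM) to a
  `feature_dim`-dimensional feature vector;
* the **proportion head** is an MLP (widths `mlp_dims`, then the number of
  cell types) with SiLU activations between the linear layers and a
  terminal softmax, so predictions live on the simplex by construction;
* the **expression head** is a one-dimensional U-Net: the features are
  read as a one-channel sequence, lifted to `base_channels` channels by a
  stem convolution, passed through `unet_depth` down blocks (max pool,
  then twice {convolution, batch normalization, ReLU}; each block doubles
  the channels and halves the length) and the mirrored up blocks
  (transposed convolution halving channels and doubling length, skip
  concatenation from the matching down stage, then the same two
  convolution rounds), mapped to one channel per cell type by a 1×1
  convolution, and finally projected per channel from `feature_dim` to the
  gene dimension by a shared linear map with a ReLU, so profiles are
  non-negative.

Two architectural details are deliberate choices where the design was
open.  First, nothing in the U-Net template dictates how a
length-`feature_dim` sequence becomes a length-$g$ gene profile; we give
each cell-type channel its own linear projection, which costs no extra
arithmetic over a shared map (the same matrix products run either way)
but lets every cell type keep its own gene-space offsets and loadings —
in development this was the difference between profiles that tracked
per-gene condition effects and profiles that only matched global means.
Second, skip
connections between matching down and up stages are a defining property
of the U-Net family and are included even though they are easy to omit
in a first implementation.

Both heads are trained jointly with the weighted two-term loss

$$ \lambda_p\,\mathrm{MSE}(\hat p, p)\;+\;\lambda_G\,\mathrm{MSE}(\hat G, G), $$

where the expression term averages only over cell types actually present
in a sample (the *type mask*): a type that contributed zero cells has an
all-zero target column that carries no information, so it is excluded
rather than regressed toward zero.  Defaults are $\lambda_p = 100$,
$\lambda_G = 1$; proportion squared errors live on the simplex and are two
to three orders of magnitude smaller than squared errors in log2
expression space, so the up-weighting roughly balances the two terms at
initialization.  Both weights are configuration values.

### Optimization choices that matter

Training uses Adam.  Three choices stabilise it, all fitted on training
data only and stored in the checkpoint:

1. **Per-gene input standardization.**  Log2-CPM inputs have means far
   from zero; feeding them raw drives the softmax head into its saturated
   (zero-gradient) regime at initialization, where it stays.  The model
   therefore standardizes every input with per-gene mean and standard
   deviation fitted on the training set.
2. **Small terminal-layer initialization** for the proportion head, so the
   initial prediction is near-uniform rather than a saturated one-hot.
3. **Output-bias initialization at the mean target profile** for the
   expression head, so optimization spends its budget on per-sample and
   per-type deviations rather than re-learning a global offset.

The default learning rate is $10^{-3}$ with batch size 64, a tenfold
learning-rate decay at epoch 30 (constant-rate Adam settles on a noise
floor that the decay lets the expression head drop below), at most 40
epochs and early stopping after 8 epochs without validation improvement;
the best-validation parameters are retained.  Batch normalization uses
batch statistics during training and running statistics at inference, so
a sample's prediction does not depend on what else is in its batch.

## The pseudobulk simulator

Supervised training needs bulk samples with known ground truth, which
real cohorts cannot provide.  The simulator draws them from an annotated
single-cell reference:

* cells are split 8:1:1 into train/validation/test, stratified by cell
  type (and condition) so no type is missing from any split and no cell
  leaks between training and evaluation;
* per sample, a proportion vector is drawn from a Dirichlet — symmetric
  with $\alpha = 25$ (near-even proportions) or with $\alpha = 7$ on one
  uniformly chosen type and 1 elsewhere (one dominant type); training
  sets mix both regimes half and half;
* integer per-type cell counts come from a multinomial over
  `cells_per_sample` draws (default 500), cells are sampled with
  replacement within type, and the pseudobulk vector is the mean raw
  count over all sampled cells; the target proportions are the realized
  multinomial fractions, not the Dirichlet draw;
* the ground-truth profile of each present type is the mean raw count of
  its sampled cells, so in count space $G\,p = b$ holds *exactly* by
  construction — this identity is asserted to $10^{-9}$ in the tests;
* inputs and targets then pass through the normalization
  $\log_2(10^6\,x/\mathrm{sum}(x) + 1)$; profile columns are normalized
  per column, mirroring how a real per-type profile would be normalized;
* with several references, a quarter of training samples pool cells
  across all of them, emulating the cross-batch mixing used to blunt
  reference-specific batch effects.

Averaging raw counts and normalizing afterwards (rather than averaging
normalized per-cell values) is one of two defensible readings of
"average expression of sampled cells"; it is the one that preserves the
exact count-space identity, and it is recorded here as a package
decision rather than asserted as the only reading.

## The synthetic reference generator

Tests and the acceptance experiments run against generated references
with planted, recoverable structure: negative-binomial counts (variance
$\mu + 0.5\mu^2$ by default) around log-normal per-gene baselines;
per-type marker sets (default 40 genes per type at fold change 8,
disjoint across types); and optionally a second condition that
multiplies a disjoint per-type set of genes (default 30 at fold 4) in
condition-2 cells.  Defaults — 6 cell types, 1000 genes, 300 cells per
type — were fixed once as the study conditions for all recovery
experiments.

What the generator does *not* emulate: batch effects between platforms,
gene-length bias, read-level noise, correlated gene modules, or the
heavy zero inflation of shallow droplet data.  A passing recovery test
therefore shows that the estimator inverts the generative model it was
trained under at realistic noise levels — it does not certify accuracy
on any particular real tissue.

## Marker selection

Input genes are chosen per reference by a one-vs-rest Wilcoxon rank-sum
test on per-cell log2-CPM expression (tie-corrected normal
approximation, cross-checked against `stats::wilcox.test` in the test
suite), Benjamini–Hochberg adjustment *within each cell type's* family
of tests, a positive log-fold-change requirement, ranking by log fold
change with ties broken by gene identifier, and a per-type cap
(`top_n`).  The union over types and references, intersected with the
genes available in the target bulk matrix, fixes the model's input and
output coordinates.  The BH family scope (per cell type rather than
global) matches what the per-type selection implies; selection is fully
deterministic.

## Evaluation metrics

Lin's concordance correlation coefficient
$\rho_c = 2\rho\sigma_x\sigma_y / (\sigma_x^2+\sigma_y^2+(\mu_x-\mu_y)^2)$
is the headline proportion metric: unlike Pearson's $\rho$ it penalises
scale and location shifts, so $|\rho_c| \le |\rho|$ with equality only at
matched moments.  All moments are population ($1/N$) moments so that
$\rho_c(x,x)=1$ exactly.  The L1 error is the plain mean absolute
difference.  The linear-fitting score is
$R^2 = 1 - \sum_i(y_i-x_i)^2 / \sum_i(x_i-\bar x)^2$: 1 for a perfect
prediction, 0 for the constant prediction at the truth's mean, negative
when worse than that; the squared denominator is the only reading
consistent with the constant-prediction anchor.

## Cell-state subtyping

Given per-patient predicted profiles, the subtyping pipeline is:

1. **Binary cell states.**  Per cell type, patients are clustered on that
   type's predicted profile (Leiden on a 15-nearest-neighbour graph, the
   resolution binary-searched to exactly two clusters; a Ward
   hierarchical two-way cut is the logged fallback).  State 0 is the
   larger cluster, which makes repeated runs identical.
2. **Definition enumeration.**  A *group definition* picks $k$ of the $c$
   cell types and one required state per picked type; patients matching
   all constraints form one group, everyone else the other.  Definitions
   inducing the same unordered partition are counted once; with all
   $2^c$ state combinations populated there are $3^c - 1 - c$ distinct
   definitions — 722 for six types, the package's printed combinatorial
   anchor.
3. **Survival screening.**  A two-group log-rank test per definition,
   BH-adjusted across all tested definitions, keeping adjusted
   $p < 0.05$; groups smaller than 5 patients (configurable) are not
   tested.
4. **IoU merging.**  Pairwise similarity
   $\max(\mathrm{IoU}(A_1,B_1), \mathrm{IoU}(A_1,B_2))$ over each
   definition's smaller group, binarized at 0.8; connected components of
   the resulting graph group near-duplicate definitions.
5. **Consensus.**  Within a component, the definition with the smallest
   log-rank p-value anchors the orientation; every other definition's two
   indicator encodings are paired with the anchor's by minimal Hamming
   distance (exact ties pair with the first encoding, and are logged).
   A patient joins a consensus group on a strict majority of the
   aligned assignments and is otherwise unresolved; of the two candidate
   orientations, the one with fewer unresolved patients wins.
6. **Direction labelling and final merge.**  Each component's consensus
   is labelled favorable or unfavorable by comparing the restricted-mean
   survival of its smaller group against the rest (median survival is
   the configurable alternative); same-direction consensuses are merged
   by another strict-majority vote; patients claimed by both final
   groups are moved to the remainder and logged.
7. **External transfer.**  Per direction, signature genes
   (rank-sum, BH < 0.05, capped at 200 by |logFC|) feed a one-component
   PCA fitted *separately per cohort*, with the test component's sign
   aligned to the training cohort by correlating gene loadings, since a
   one-component PCA sign is arbitrary; a logistic regression on the
   training component then classifies the external cohort.

## Problem sizes used by the recovery experiments

The acceptance experiments run the full loop — generate a reference,
select markers, simulate, train, deconvolve held-out samples — at the
package's chosen desk scale: 6 cell types, 1000 genes (about 350–450
after selection), 2000 training / 200 validation / 200 test pseudobulk
samples, `feature_dim` 128 with `mlp_dims` (128, 64) and the full
4-block U-Net depth.  These sizes recover proportions at CCC above 0.97
and per-type profiles at Pearson above 0.9 in a few minutes of CPU time;
the full-scale defaults (`feature_dim` 4096, MLP widths 4096–1024–256–64)
remain the `model_config()` defaults for real-data use.

## Numerical notes and limitations

* All convolution arithmetic runs through compiled RcppArmadillo
  kernels; pure-R reference implementations of the same kernels stay in
  the package and the test suite asserts their agreement, alongside a
  finite-difference check of the entire backward pass.
* Every stochastic step — generation, splitting, simulation, parameter
  initialization, shuffling, clustering — is seeded; identical seeds give
  bit-identical results on the same platform.
* The Leiden resolution search can legitimately fail (e.g. identical
  patient profiles); the fallbacks are deterministic and always logged.
* Zero-variance inputs to the correlation-based metrics raise errors
  rather than returning NA, because a silent NA propagates into
  screening decisions.
* The deconvolution model is reference-bound: it predicts the cell types
  it was trained on, in the gene space it was trained on, and a bulk
  cohort from a different tissue or condition distribution is outside
  its warranty.  Transfer to an external cohort assumes shared gene
  identifiers and a comparable signature direction.
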