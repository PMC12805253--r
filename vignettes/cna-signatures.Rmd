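---
title: "Attention-based multiple-instance learning for CNA signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multiple-instance learning for CNA signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnamil)
```

## Data model

`cnamil` works on gene-level discrete copy-number calls: a samples ×
genes integer matrix with values in {−2, −1, 0, 1, 2} — deep loss,
shallow loss, diploid, low-level gain, high-level amplification — the
five-level coding produced by GISTIC-style calling and distributed by
cBioPortal. Matrices are validated on construction (`cna_matrix()`):
out-of-range, non-integer or missing cells are rejected rather than
imputed, because no principled missing-data rule exists for discrete
calls; absent genes can instead be filled as diploid (0, the neutral
call) when two cohorts are aligned with
`align_gene_sets(policy = "union_fill_zero")`. The default alignment
policy is `"intersect"`, since a shared gene set is what downstream
comparison metrics assume. Gene annotations use 0-based half-open
coordinates (BED convention) and map each gene to one chromosome arm.

## The classification model

### Why multiple-instance learning

CNA profiles of one cancer type vary substantially between patients:
subclonal events, subtype structure and sporadic passengers make
single-sample classification noisy. We therefore attach labels to
*bags* — collections of K patient profiles of one type — and let the
model decide which instances carry the type-defining pattern. Because
training bags are homogeneous, the classical MIL assumption (the bag
label is the maximum over latent instance labels) holds trivially; what
MIL buys here is the attention mechanism's ability to down-weight
atypical samples inside a bag.

### Architecture

Each instance `x_k` (a D-vector of selected-gene calls) is embedded by
`f_ψ`, one hidden affine layer with ReLU followed by an affine map to
width M. Instances never interact before pooling. The bag embedding is

    z = Σ_k a_k h_k,
    a_k = softmax_k( wᵀ [ tanh(V h_k) ⊙ σ(U h_k) ] ),

with V, U ∈ R^{L×M} and w ∈ R^L: a tanh branch gated elementwise by a
logistic sigmoid, then projected to a scalar score and normalized over
the bag. The gate lets the model modulate *how much* of each embedding
direction contributes, which a plain tanh attention cannot. A final
affine + softmax head `g_φ(z)` produces class probabilities, and the
training loss is the multinomial bag negative log-likelihood
`−log p[y]`, clamped at 1e−12 to stay finite. Pooling by a weighted sum
of per-instance terms makes the whole composition permutation-invariant,
and duplicating all instances leaves predictions unchanged because the
softmax renormalizes.

This is the smallest architecture consistent with nonlinear instance
embeddings and gated attention; no deeper variant is needed to separate
block-structured CNA classes. Defaults M = 128, L = 64 suit
thousands-of-genes inputs; the examples and tests use M = 32, L = 16,
which is ample after feature selection. Argmax ties anywhere resolve to
the lowest class index.

### Training

`train_mil()` minimizes mean bag NLL with Adam (learning rate 1e−3,
weight decay 1e−4 on weight matrices and the attention projection, not
on biases). Bags are regenerated each epoch from epoch-derived seeds;
the default scheme draws the same number of bags per class
(`"equal_bags"`), which equalizes gradient exposure across classes —
the safer choice under the order-of-magnitude class imbalance of
pan-cancer cohorts, where rare types are the ones that suffer. Weights
initialize from N(0, 0.01²), so a fresh model predicts near-uniform
probabilities and the first-epoch loss starts at about log C. With a
validation cohort, early stopping monitors held-out bag NLL (patience
10) and returns the best parameters. Gradients are computed by an
explicit reverse pass whose correctness is pinned to central finite
differences at 1e−4 relative tolerance in the test suite. All
arithmetic is single-threaded base-R linear algebra, so runs are exactly
reproducible from the seed.

## Feature selection

`rfecv_select()` implements recursive feature elimination with
stratified cross-validation: per round, the estimator is fit on the full
training cohort to rank features, the mean CV score of the current set
is recorded, and the lowest `ceiling(step_fraction × remaining)`
features are dropped, down to `min_features`. The selected set is the
evaluated set with maximal mean CV score, ties resolved toward fewer
features (parsimony). Defaults: ridge-penalized multinomial logistic
regression (glmnet, fixed λ = 0.05, no standardization — the discrete
calls share one scale), per-feature importance = sum over classes of
absolute coefficients, balanced accuracy as the score, 5 folds, step
fraction 0.1. Balanced accuracy is preferred over plain accuracy for the
same imbalance reason as bag balancing. A random-forest backend
(`"tree_ensemble"`, impurity importance) is available for cohorts where
linear importance is implausible.

One behavior deserves emphasis: on cohorts that are separable —
including this package's simulated cohorts at default noise — the CV
score saturates at exactly 1.0 for small informative subsets, so the
parsimony tie-break selects a handful of genes rather than every
informative one. That is the argmax contract working as specified, not
a recovery failure; what is guaranteed (and tested) is that the
surviving genes are planted signal, not background. When the goal is
signature generation over *all* discriminative genes, train on the full
gene set or raise `min_features`.

## Signature generation

After training, `instance_predictions()` gives every instance its
attention weight `w_i` within its bag and class probabilities `p_i`
from running the model on the singleton bag {x_i} — the minimal
instance-level readout consistent with the architecture, since the
model's only probability-producing path is the full composition. The
normalized weighted score `p̂_i = (w_i / Σ_j w_j) · p_i` sums to 1 over
the instances and classes of a bag, and the predicted class
`ĉ_i = argmax_k p̂_ik` equals `argmax_k p_ik` because positive scaling
preserves the argmax.

The projection of predictions onto genes is

    s_gk = mean over {i : ĉ_i = k} of p̂_ik · x_ig,

normalized per class by the maximum absolute score (so top genes score
±1; `"l1"` is available). This rule was chosen because it is linear in
the instance predictions, inherits the sign of the underlying calls —
recurrently gained genes score positive (duplication-associated), lost
genes negative (deletion-associated) — and provably recovers planted
blocks on simulation. An alternative gradient-times-input attribution
(`project_gradient_input()`) is exposed behind the same contract for
users who prefer model-gradient evidence over value-weighted evidence;
the two agree on block recovery in the tests. `extract_signature()`
keeps the N highest-|score| genes per class (default N = 50; ties break
alphabetically for determinism), with direction dup/del from the score
sign.

## Comparison metrics

`frequency_profile()` counts, per gene, the fraction of samples with a
gain (call ≥ 1) and a loss (call ≤ −1), merging low- and high-level
events as Progenetix-style frequency tracks do; `high_level_only = TRUE`
restricts to ±2. `aggregate_to_arms()` takes the unweighted mean per
chromosome arm (no gene-length weighting — with gene-level calls every
gene is one observation), and `arm_spearman()` rank-correlates the
arm-level net score (mean gain − mean loss) over shared arms, with
average ranks for ties. Net score is used as the single arm statistic
because it orders arms by their dominant aberration direction, which is
what visual gain/loss concordance captures; gain-only or loss-only
tracks can be correlated by passing the respective columns as named
score vectors. `signature_jaccard()` is plain set overlap
|A∩B| / |A∪B|.

## The simulator

`simulate_cohort()` emulates the data model above: each class carries
`blocks_per_class` contiguous planted gene blocks (default 2 blocks of
10 genes, one gain and one loss); a sample of the class harbors each
block with probability `penetrance` (default 0.9 — near-clonal, as
driver arm-level events are within a type); a carried block is ±2 with
probability `high_level_fraction` (default 0.3), drawn once per block
since a segmental event has one level; background noise is a sporadic
nonzero call per gene at `background_rate` (default 0.02). Planted
values overwrite background at the same locus because a gene's call is
a single observed state. Blocks of different classes occupy disjoint
intervals (validated); contiguity makes arm-level aggregation of
simulated data meaningful. Subtypes with their own block sets —
including co-occurring pairs mimicking known co-deletions — can be
planted per class, each block still carried independently at the
penetrance rate. A uniform annotation (50 genes per simulated
chromosome, arms split at the midpoint) accompanies every cohort.

What the simulator does *not* model: allele-specific or continuous
log-ratio data, tumor purity and ploidy, correlated (segment-length)
noise, overlapping aberrations shared between classes, and label noise.
Tests passing on simulated cohorts therefore demonstrate that the
machinery is correct and recovers planted structure under realistic
sparsity — not that real pan-cancer accuracy will match; real cohorts
are far from separable and their class-discriminative events overlap.

## Problem sizes and numerical choices

The test suite and the acceptance script use 3-class cohorts of 40
samples per class over 500 genes (penetrance 0.95, background 0.01 for
the recovery checks), bags of K = 10, models of M = 32, L = 16, up to 50
training epochs, and 10 simulation seeds for averaged recovery metrics —
sizes at which every stage's behavior is already unambiguous and a full
run completes in seconds. Stage seeds derive from one global seed by a
32-bit FNV-1a hash of the stage name, so stages are statistically
decoupled but jointly reproducible; artifacts are stamped with a hash of
the scientific configuration (paths excluded) plus the seed, and reruns
with an identical configuration are byte-identical. Degenerate inputs
fail loudly by design: empty gene intersections, single-sample classes
(warned and kept in training), bags narrower than the model, probability
0 at the label (clamped and logged), fewer than 3 shared arms.

## Known limitations

* Instance probabilities come from singleton bags; with strongly
  bag-size-dependent attention, singleton behavior may differ from
  in-bag behavior. The attention-normalized scores mitigate but do not
  remove this.
* The projection rule weights an instance's own calls; a gene never
  aberrant in predicted members of a class scores exactly 0 even if its
  *absence* is discriminative.
* RFECV's parsimony tie-break under score saturation (above) means the
  selected set is a minimal discriminative subset, not an exhaustive
  catalog of class-associated genes.
* Training is plain single-threaded R; it is comfortable up to a few
  thousand selected genes and a few hundred bags per epoch, and is not
  intended for GPU-scale experiments.
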