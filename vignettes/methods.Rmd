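---
title: "From abundance tables to interpretable images: methods and design"
author: "taxapix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From abundance tables to interpretable images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Gut microbiome profiles are sparse compositional tables: hundreds to
thousands of taxa, relative abundances summing to one per sample, most cells
zero. Deep models can classify phenotypes from such tables, but a flat
vector of taxa discards what we know about *which taxa resemble each other*,
and most architectures give no usable account of which taxa drove a
prediction. taxapix addresses both: taxa are embedded into a plane by
functional similarity, every sample becomes a single-channel image over one
fixed taxon-to-pixel layout, a residual convolutional network with spatial
attention classifies the images, and Grad-CAM saliency is mapped back
through the layout to score every taxon — with downstream summaries of the
metabolites and functional traits of the important taxa.

# The pipeline, stage by stage

## Taxa similarity (`buildFeatureMatrix`, `correlationDistance`, `copheneticDistance`)

Four similarity sources are supported, mirroring the comparisons usual in
this workflow family:

* **metabolic** — rows of a taxa x metabolite annotation table used as
  feature vectors, unchanged. The annotation resource itself *is* the
  similarity; no computation on the samples is needed, and taxa missing from
  the table are kept with all-zero vectors so the layout covers every
  observed taxon.
* **abundance** — per-taxon standardized abundance profiles across samples.
* **combined** — column-wise z-scored concatenation of both blocks, so
  neither block dominates by scale.
* **pearson / spearman / cophenetic** — pairwise distances
  (`1 - r` of abundance profiles, or patristic distance on a supplied
  phylogeny) fed to the embedder through its precomputed-distance pathway.

Zero-variance taxa get correlation distance 1 to everything (the `r = 0`
convention): embeddings need finite inputs, and an uninformative taxon
should sit at an uninformative distance rather than propagate `NaN`.

## 2D embedding (`embedTaxa`)

Exact (quadratic-cost) t-SNE and a UMAP-style embedder are implemented in
the package. At the problem sizes this tool targets (hundreds of taxa, at
most a few thousand) the O(n^2) cost is negligible and exactness simplifies
testing. Both are deterministic given a seed.

* t-SNE: per-point precision calibrated by binary search to the target
  perplexity (default 30), early exaggeration 12 for the first third of the
  300 iterations, momentum 0.5 then 0.8, gain-adaptive gradient descent.
* UMAP-style: smooth-kNN graph (default 15 neighbors) with per-point
  bandwidth solving `sum exp(-(d - rho)/sigma) = log2(k)`, fuzzy union
  symmetrization, kernel parameters `a, b` fitted to the `min_dist` curve
  (default 0.1), spectral initialization from the normalized graph
  Laplacian, and full-batch gradient descent on the UMAP cross-entropy with
  gradient clipping at 4 and a linearly decaying step (0.5 to 0). The
  reference implementation optimizes the same objective by edge-sampling
  SGD; full-batch descent is deterministic and fast at these sizes, which
  we prefer for reproducibility.

## Fixed pixel layout (`minAreaRectangle`, `assignPixels`)

The minimum-area enclosing rectangle of the embedded points is found by
rotating calipers: the optimum has an edge collinear with a convex-hull
edge, so evaluating the axis-aligned bounding box at each hull-edge angle is
exact. The embedding is rotated into the rectangle frame and binned onto an
H x W grid (default 32 x 32); bins are half-open with the far edge clamped
into the last pixel, and a degenerate (collinear) axis is padded to 1e-6 of
the long axis. Multiple taxa may share a pixel; the collision count is
logged and carried in the map, because it bounds the resolution of any
back-projected importance: co-located taxa are indistinguishable to the
model and always receive tied scores.

## Rendering (`renderImages`)

A pixel's value is the *sum* of the relative abundances of its taxa. Summing
(rather than mean or max) preserves compositional mass exactly — before
normalization every image sums to 1, an invariant asserted in the tests.
The whole stack is scaled by one global maximum computed on the training
set and reused for held-out data; a per-image maximum would erase
between-sample differences and break train/test comparability.

## The classifier (`buildModel`, `trainModel`)

Each residual block runs, in order: convolution, batch-normalization,
activation, convolution, batch-normalization, spatial attention, identity
shortcut addition, activation. The spatial attention gate pools channels
into per-location mean and max maps, convolves them with a single k x k
filter (default 7) and applies a logistic, multiplying the resulting
(0, 1) map into the main branch before the shortcut addition — the standard
CBAM-style realization of a spatial attention map at that position. The
shortcut is a 1 x 1 strided convolution with batch-normalization whenever
the stride or channel count changes shape. Blocks are specified as a plain
list of `(nFilters, kernelSize, stride)`.

Two design choices depart from the most common image-classification
defaults, both for the same reason: these are *fixed-layout* images in
which the discriminative signal sits at specific pixels.

* **Flatten head (default).** The last block's feature map is flattened
  into the linear softmax head, giving the classifier position-specific
  weights. Global average pooling (`headType = "gap"`) is available but
  position-blind: on simulated data whose signal is a fixed set of pixels
  shifting mass coherently, a pixel-wise linear model separates classes
  easily while any spatially pooled statistic carries almost no class
  information, so a GAP-headed network cannot reach the accuracy that a
  plain linear model on pixels already attains. Flattening restores the
  representational floor of the linear model while keeping the
  convolutional features and the attention gates.
* **Per-pixel input standardization (default on).** Pixel values are
  location-wise standardized with training-set means and standard
  deviations (stored in the model, applied to all later inputs). Raw pixel
  values span orders of magnitude across the image; standardization puts
  every informative pixel on the same footing, exactly as one standardizes
  features for any tabular model.

Training minimizes cross-entropy (optional inverse-frequency class weights)
with Adam (default learning rate 1e-3; the worked examples and acceptance
runs use 3e-3, which converges in a few dozen epochs on images of this
size), batch 32, early stopping on the loss of a stratified validation
split (fraction 0.2, patience 10), restoring the best-validation
parameters. All randomness — initialization, split, shuffling — derives
from the config seed, so a fold retrains identically.

## Cross-validation (`crossValidate`)

Stratified k-fold (optionally repeated). Everything fit from data — the
similarity input in sample-dependent modes, the embedding, the pixel
layout, the image normalization constant, the input standardization, the
network — is computed on the training folds only and applied unchanged to
the held-out fold.

## Saliency and back-projection (`gradCAM`, `classSaliency`, `taxaImportance`)

Saliency combines the chosen block's feature maps (default: the last
block's output, i.e. its post-attention map after the shortcut) with the
class-score gradient, keeps the positive part, upsamples bilinearly
(nearest-neighbor available for exact pixel bookkeeping) and normalizes to
max 1. The default weighting multiplies gradient and activation element by
element before summing channels; the classic pooled weighting (channel
weights = spatial mean of the gradient) is available as
`method = "pooled"`. The two coincide exactly under a GAP head, but under
the flatten head the pooled form averages away the position-specific
gradients and can highlight the wrong regions entirely, inverting the
recovery of spiked taxa on simulated data; the faithful element-wise form
is therefore the default (the acceptance suite asserts the recovery it
achieves). Class-level saliency averages
per-sample maps — each first normalized to max 1, then the average is
renormalized; this equalizes samples' contributions and is flagged here as
a convention, since averaging before normalization is equally defensible.
Back-projection assigns every taxon its pixel's saliency; co-located taxa
tie by construction and the shared-pixel count is reported. "Important"
taxa are those at or above the 90th percentile of nonzero scores by
default (`percentile` exposed); ties at the threshold are included. An
occlusion saliency (probability drop when zeroing each pixel) is provided
as an independent, model-agnostic cross-check.

## Downstream interpretation (`metaboliteSums`, `differentialMetabolites`, `traitSummary`)

Metabolite sums over a group's important taxa are column sums of the
annotation table (producer counts for binary annotations), filtered at the
99th within-group percentile by default. Differential metabolite analysis
between important and unimportant taxa uses per-metabolite log2 fold
changes of mean annotation weight with pseudocount 1e-3, a rank-sum test
(t-test switchable) and Benjamini-Hochberg adjustment — the columns needed
for volcano and MA views. A rank-sum test is the conservative default for
binary/weighted annotation columns, where normality is indefensible. Trait
summaries count gram status, motility and oxygen tolerance per taxa set —
taxa absent from the trait table count as "unknown" so set sizes are
conserved — plus the median gene count over known values.

# The simulator (`simParams`, `simulateCounts`)

The generator emulates sparse compositional 16S gut profiles so the whole
pipeline is testable offline:

* a long-tailed community template (renormalized lognormal intensities,
  sigma 1.5, drawn once from the seed) or a user template;
* per-sample, per-taxon gamma intensity noise at a stated coefficient of
  variation (default 0.3);
* differential abundance: a chosen taxa subset multiplied by a fold change
  in the non-control classes, renormalized (so "DA" means a compositional
  shift, as in spike-in benchmarks);
* sparsity: independent per-sample taxon dropout, with the dropout rate
  calibrated by two pilot rounds and a secant correction so the realized
  zero fraction (dropout plus sampling zeros) matches the target in
  expectation — the emulated studies report sparsity levels (0.78-0.89),
  not a mechanism, so the mechanism is ours;
* counts: exactly `librarySize` reads drawn compositionally. The urn
  construction (largest-remainder apportioning of `urnFactor x librarySize`
  balls, sampling without replacement) realizes the multivariate
  hypergeometric; at the default urn depth of 100 libraries the multinomial
  is statistically indistinguishable and is used (recorded in metadata),
  with the exact urn sampler engaged for `urnFactor < 100`;
* optional cohorts: labels become the phenotype x cohort cross, with
  cohort-specific lognormal template perturbations (sigma 0.3) emulating
  geographic signal.

Matching annotation tables place a block of "signal" metabolites produced
by DA taxa with high probability (default 0.9) against a background rate
(0.2), and trait tables draw categorical traits with a 10% "unknown" rate
and uniform gene counts in [1000, 8000].

What the simulator does **not** emulate: phylogenetic correlation among
taxa, taxon-taxon interaction structure, batch effects, variable library
sizes, or annotation databases' realistic sparsity patterns. Tests passing
on simulated data therefore demonstrate mechanical and statistical
correctness of the pipeline — signal recovery, calibration under the null,
robustness to embedding parameters — not performance on any real cohort.

# Numerical choices and degenerate inputs

* Correlation distances are clamped symmetric with zero diagonal; values
  live in [0, 2]. Numerically constant profiles (sd below 1e-12) count as
  zero-variance.
* The rectangle search breaks area ties toward the first hull edge
  examined; a single-point or collinear embedding produces a degenerate
  rectangle whose short axis is padded before binning.
* Pixels on the far rectangle edge clamp into the last bin.
* Batch-normalization uses eps 1e-5 and momentum 0.9; statistics are
  frozen at evaluation.
* The attention max-pool routes gradients to the arg-max channel only;
  ties go to the lower channel index.
* Probabilities are floored at 1e-12 inside the cross-entropy.
* All stage seeds derive from one root seed by fixed offsets, kept below
  2^31.

# Scales used in the test suite

The packaged tests and the acceptance script run the study conditions at
desk scale, chosen once: 200 taxa, 60 samples per class, library size
10,000, sparsity 0.8, 45 DA taxa; images 16 x 16 with blocks
(16, 3, 1), (32, 3, 2), stem 8, attention kernel 7, Adam 3e-3 for at most
30 epochs; t-SNE perplexity 30 (sweeps 5-50), UMAP neighbors 5-25. The
32 x 32 default image size targets real datasets with more taxa; at 200
taxa a 16 x 16 grid leaves about one taxon per occupied pixel, which is
what the importance back-projection needs.

# Known limitations

* Taxon identifiers join by exact string match; no taxonomy harmonization.
* Annotation coverage limits interpretation: taxa without annotations
  embed from zero vectors and cluster together.
* Co-located taxa are fundamentally indistinguishable in importance; use
  larger images to separate them, at higher compute cost.
* The embedders are exact/quadratic: comfortable to a few thousand taxa,
  not beyond.
* Saliency explains the trained model, not biology: a taxon can score high
  because it co-locates with informative taxa.
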