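---
title: "Multi-modal tumor segmentation with hybrid attentional fusion and masked self-supervision"
author: "hafnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal tumor segmentation with hybrid attentional fusion and masked self-supervision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gliomas are delineated on multi-parametric MRI: four co-registered
acquisitions (T1, contrast-enhanced T1, FLAIR, T2) image the same anatomy
with complementary tissue contrast. BraTS-style reference data label each
voxel as background (0), necrotic/non-enhancing tumor core (1),
peritumoral edema (2) or enhancing tumor (4), and segmentations are judged
clinically on three nested region compositions: whole tumor
WT = {1, 2, 4}, tumor core TC = {1, 4} and enhancing tumor ET = {4}.
No single sequence separates all tissue classes — enhancing tumor lights
up on T1CE, edema on FLAIR, core and edema on T2 — so a segmentation
network benefits from modality-specific feature extraction followed by an
explicit fusion step. This package implements such a network, its
self-supervised training scheme, the BraTS preprocessing around it, and a
synthetic phantom generator so the whole method runs and is tested at desk
scale without any external download.

## Backbone: multi-modal residual encoder–decoder

Each modality gets its own encoder. The building blocks are

* `Conv(x) = ReLU(BN(phi_3x3(x)))` — a 3×3 convolution (no additive bias;
  batch normalisation supplies the shift), batch norm, ReLU;
* `ResConv(x) = phi_1x1(x) + Conv2(DP(Conv1(x)))` — a residual unit whose
  1×1 projection carries the identity path to the new channel width, with
  dropout (default rate 0.2) between the two conv blocks;
* an encoder layer `EL(x) = MP(ResConv(x))`, max pooling 2×2/stride 2.

Four such layers halve the spatial side each time, so a 224×224 slice
reaches the bottleneck at 14×14 — 1/16 of the input — while channels grow
as 32, 64, 128, 256 from `baseFilters = 32`. Each encoder ends in an
atrous spatial pyramid (ASPP): parallel 3×3 convolutions at dilations 1,
6, 12, 18 plus a global-average-pooling branch, concatenated and projected
back to the input width by a 1×1 conv block. The decoder mirrors the
encoder with 2×2/stride-2 transposed convolutions
(`DL(x) = ResConv(TransConv(x))`) and a final 3×3 convolution to the four
class-score channels at full resolution.

## Hybrid attentional fusion in the skip connections

At every encoder depth the n per-modality skip maps (C channels each) are
fused before entering the decoder:

    F = [ sum_i m_i ; prod_i m_i ; max_i m_i ]            (3C channels)
    HAFB(F) = phi3( F + F * sigmoid(phi2(ReLU(phi1(F)))) )

with all attention kernels 3×3; `phi1` compresses 3C→C, `phi2` restores
C→3C, and `phi3` keeps 3C. Two properties matter:

* the fused width is 3C *for any* number of modalities, so the decoder's
  size is independent of n — with the block the total parameter count is
  exactly affine in n, whereas plain concatenation (the no-fusion
  baseline, whose decoder runs at n·C widths) grows quadratically. On the
  reference configuration the block costs parameters below 3 modalities
  and saves them from 4 on;
* the fusion value is invariant to modality order. The package computes
  the sum and product parts in elementwise-*sorted* value order, so the
  invariance holds bit-exactly rather than up to floating-point
  reassociation. The running product is clamped at ±1e6 (products over
  many modalities can overflow); ties in the maximum route the gradient to
  the first input attaining it.

Where the attention literature is silent the block uses bare convolution →
ReLU → convolution → sigmoid for the gate (no normalisation inside the
attention module).

## Masked dual-branch self-supervision

During training a second branch receives the same case with each modality
occluded at a *different* position (distinct window origins; masks may
still overlap partially — difference of position, not disjointness, is
what makes the modalities complementary). Both branches run through the
*same* encoders and pyramids — one parameter set, gradients accumulating
from both uses — while the decoder consumes only the clean branch. The
pretext objective is the dissimilarity of the two branches' concatenated
post-pyramid bottleneck features,

    L_sim = 1 - ( <f_clean, f_masked> + eps ) / ( |f_clean| |f_masked| + eps ),

with eps = 1e-5. The cosine form (square root of the product of squared
norms in the denominator) is used because identical branches must score
exactly 0; the variant with squared norms in the denominator — under which
identical inputs generally do not score 0 — is available via
`form = "printed"` in `similarityLoss()`. Features are compared after the
pyramid (the natural meeting point of the two branches); the comparison
point is a design choice, not a constraint of the mechanism.

Four occlusion strategies are provided (`makeMask()`): a 20×20 square
(400 px), a 50×50 square (2500 px), a grid of 4×4 = 16 squares of 5×5 on
a 10-pixel period inside a 35×35 window (400 px), and 400 distinct random
pixels inside a 35×35 window. Window origins are drawn uniformly over
valid positions under the caller's seed. Masked pixels are set to 0, the
post-normalisation background level (configurable).

## Losses, optimiser, schedule

The segmentation loss is a soft-Dice/cross-entropy mixture per batch,

    L_seg = mean_batch( alpha * L_Dice + beta * L_CE ),  alpha = 1, beta = 0.5,

where the Dice term averages the smoothed per-class soft Dice coefficient
(smoothing 1e-5 in numerator and denominator; background class included by
default) and the normaliser is the batch size — the mixture guards the
Dice term in extreme class-imbalance cases. The total objective adds
`lambdaSim * L_sim` (default weight 1), trained jointly from the start
(no separate pretext-only warm-up phase). The optimiser is Adam at initial
learning rate 1e-5, decayed ×0.9 every 5 epochs (0-based epoch indexing:
first decay at epoch 5) for 15 epochs, batch size 8 — these are the
reference full-scale settings and are the `trainConfig()` defaults. The
phantom-scale tests instead use learning rate 1e-3: at a few hundred Adam
steps from random initialisation, 1e-5 cannot move a network measurably;
the rate is an ordinary `TrainConfig` field, not a code change.

## Preprocessing

Volumes are 240×240×155. The pipeline keeps the middle 144 axial slices —
a centered window with floor rounding for the odd remainder, so depth 155
keeps 0-based indices 5..148 — and center-crops each slice to 224×224
(offset 8 per axis for a 240 input). The raw label 4 is remapped to the
internal contiguous 3 (and restored on writing). Each slice and modality
is z-scored over its nonzero (brain) pixels, with zero pixels left at 0;
normalisation is the conventional choice for this data and is exposed as a
flag since the reference protocol does not state one. Slices with an empty
brain mask are kept. The third array axis is taken as axial; NIfTI files
are keyed by the `_t1/_t1ce/_flair/_t2/_seg` suffix convention.

## Evaluation

`evaluateSegmentation()` scores WT/TC/ET with Dice, sensitivity,
specificity, and HD95 — the 95th percentile of the pooled symmetric set of
nearest-boundary Euclidean distances between region boundaries (4-connected
boundary definition; R's default quantile interpolation). Two empty
regions score Dice 1 / HD95 0; exactly one empty region scores Dice 0 and
a penalty distance defaulting to the image diagonal.

## The phantom generator

`generateCase()` draws a brain ellipse on a zero background and nests
three tumor ellipses inside it — edema (2) ⊃ core (1) ⊃ enhancing (3) —
with the whole-tumor pixel fraction driven into the requested range
(default 5–15% of the image) by axis rescaling. Each modality renders the
same geometry from a fixed class × modality intensity table chosen so that
each modality *fails* to separate at least one class pair (T1CE: core vs
brain; FLAIR: core vs enhancing; T2: core vs edema; T1: enhancing vs
brain) while the four together separate everything — this is what makes
multi-modal fusion measurably useful in the training tests. Additive
Gaussian noise (sd 0.05) is applied inside the brain only, so the
zero-background convention of the normaliser holds. Volumes stack
per-slice phantoms (slice i re-seeded as `seed + i - 1`) and emit raw
BraTS labels {0,1,2,4}.

What the phantom does *not* emulate: anatomical texture, bias fields,
partial-volume effects, registration error, 3-D tumor continuity, or
class-imbalance as extreme as real BraTS slices. Passing the phantom
learnability tests therefore demonstrates that the architecture, losses,
gradients and training loop are correct and can fit a separable
multi-modal signal — not that the network reaches clinical accuracy on
real MRI.

## Numerical and design choices

* **Autodiff engine.** No deep-learning framework is assumed: the package
  carries a reverse-mode tape with Armadillo kernels for convolution
  (im2col/col2im), transposed convolution, pooling and batch norm. Kernel
  interiors run in single precision (halved memory traffic, `sgemm`);
  activations and parameters cross the R boundary in double. Gradients
  are verified against central differences in the test suite at
  tolerances appropriate for float arithmetic.
* **Channel plan.** Encoder layer 1 outputs `baseFilters` (the layer-1
  width follows the initial-kernel setting; later layers double — the two
  statements in the block definitions are reconciled in favour of
  `baseFilters` at layer 1). Decoder and merged bottleneck run at k times
  the encoder widths with k = 3 (fusion), n (plain multi-modal), 1
  (single-encoder); ASPP branches keep the input width. Absolute parameter
  totals depend on these unstated widths, so the tested quantities are the
  scaling *laws* (exact first/second differences and the crossover), not
  absolute counts.
* **Initialisation.** He-scaled normal for convolutions feeding batch
  norm, variance-preserving (gain 1) for bare convolutions, and a
  small-scale (gain 0.01) classification head so training starts from
  near-uniform class scores.
* **Batch norm** uses biased batch variance, momentum 0.1 running
  statistics, eps 1e-5; inference mode uses the running statistics, so a
  freshly built network maps zero input to zero output.
* **"M" in the segmentation loss** is read as the batch size (batch
  mean); dropout rate 0.2, transposed-conv kernel 2/stride 2, max-pool
  2/2 where unstated.
* **Single-encoder mode** concatenates the modalities as input channels
  of one encoder — its parameter count varies only through the first
  convolution, reproducing the near-constant single-modal column of the
  parameter-scaling comparison.
* **Problem sizes in the tests.** The learnability checks train on 200
  phantom slices of side 64 with 8 base filters for 10 epochs and
  evaluate on 50 held-out slices (WT Dice > 0.7, with and without
  self-supervision), chosen as the smallest setting where the full
  multi-modal pipeline — 4 encoders, pyramids, fusion, dual branch — is
  exercised end to end; gradient checks and shape laws run on reduced
  widths since they are width-independent.

## Known limitations

2-D slices only (the reference protocol trains on slices); no mixed
precision on the R side; no bias-field or registration preprocessing
(inputs are assumed co-registered and skull-stripped, as in BraTS); the
HD95 boundary distance is exact pairwise rather than distance-transform
based, which is fine at slice scale but quadratic in boundary length;
checkpoints are R serialisations, not an interchange format.
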