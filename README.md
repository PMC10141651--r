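# hafnet

Multi-modal MRI brain-tumor segmentation in R: a residual encoder–decoder
with per-modality encoders, atrous-pyramid bottlenecks, hybrid attentional
fusion in the skip connections, and a masked dual-branch self-supervised
pretext task — plus BraTS-style NIfTI preprocessing, combined
soft-Dice/cross-entropy training, WT/TC/ET evaluation, and a synthetic
phantom generator so the entire method runs and is tested on a laptop
without any data download.

## Who this is for

Researchers working on multi-parametric MRI segmentation (BraTS-style
data: co-registered T1, T1CE, FLAIR, T2 volumes of 240×240×155 with labels
0 background, 1 necrotic/non-enhancing core, 2 edema, 4 enhancing tumor)
who want a self-contained, fully inspectable R implementation of
attention-gated multi-modal fusion with masked self-supervision — the
package carries its own reverse-mode autodiff engine with Armadillo
convolution kernels, so there is no Python or GPU dependency.

## The model

Each modality m has its own encoder built from residual units

    Conv(x)    = ReLU(BN(φ₃ₓ₃(x)))
    ResConv(x) = φ₁ₓ₁(x) + Conv₂(DP(Conv₁(x)))
    EL(x)      = MaxPool₂ₓ₂(ResConv(x))

Four layers reduce a 224×224 slice to a 14×14 bottleneck (1/16), where an
atrous spatial pyramid (dilations 1, 6, 12, 18 + global-pooling branch)
captures multi-scale context per modality. Skip connections fuse the n
per-modality feature maps (C channels each) through the hybrid attentional
fusion block

    F       = [ Σᵢ mᵢ ; Πᵢ mᵢ ; maxᵢ mᵢ ]                (3C channels)
    HAFB(F) = φ₃( F + F ⊙ σ(φ₂ ReLU(φ₁ F)) )

whose output width 3C is independent of the number of modalities — with
the block the parameter count is exactly affine in n; plain concatenation
makes it quadratic. The decoder mirrors the encoder with stride-2
transposed convolutions and ends in a 3×3 convolution to the four class
scores.

Training is joint: the segmentation loss mean(α·Dice + β·CE) over the
batch (α = 1, β = 0.5, Adam, batch 8, lr 1e-5 decayed ×0.9 every 5
epochs) plus a self-supervised term — every modality of a second branch is
occluded at a *different* position (20×20 block by default; 50×50, a 16 ×
5×5 grid, or 400 random pixels in a 35×35 window are alternatives), both
branches share the encoders, and the cosine dissimilarity of their
bottleneck features,

    L_sim = 1 − (⟨θ(x), θ(x′)⟩ + ε) / (‖θ(x)‖‖θ(x′)‖ + ε),   ε = 1e-5,

pushes the encoders toward occlusion-invariant, cross-modal features.
Evaluation reports Dice, sensitivity, specificity and HD95 (95th-percentile
symmetric boundary distance) on the clinical region compositions
WT = {1,2,4}, TC = {1,4}, ET = {4}.

## Worked example

Train on synthetic multi-modal phantoms (nested tumor sub-regions with
modality-specific contrast, so fusion genuinely helps) and evaluate on
held-out cases:

```r
library(hafnet)
train <- phantomDataset(64, phantomSpec(imageSide = 64, seed = 100))
hold  <- phantomDataset(16, phantomSpec(imageSide = 64, seed = 900))
cfg <- networkConfig(baseFilters = 8)
fit <- trainNetwork(train, cfg,
                    trainConfig(epochs = 8L, initialLr = 1e-3, seed = 7,
                                maskStrategy = "block20"))
fit
#> segFit: 8 epochs on 64 cases (batch 8)
#>   seg loss 1.0621 -> 0.0877; sim loss 0.2587 -> 0.0205
evaluateOnDataset(fit, hold)$mean
#>   region      dice sensitivity specificity     hd95
#> 1     WT 0.9830826   0.9893894   0.9968778 1.088388
#> 2     TC 0.6552546   0.4936755   1.0000000 3.848708
#> 3     ET 0.8097450   0.6908062   1.0000000 1.625787
```

The segmentation loss falls from 1.06 to 0.09 over eight epochs while the
pretext (similarity) loss falls from 0.26 to 0.02 — the shared encoders
become invariant to the per-modality occlusions — and the held-out whole
tumor is recovered at Dice 0.98. `predictCase(fit, case)` returns a label
map in the raw BraTS encoding {0,1,2,4};
`countParameters(networkConfig())` gives the reference network's exact
learnable-value count (67.45 M; 83.16 M without the fusion block — the
block saves parameters from 4 modalities on).

Real BraTS-style cases on disk are read with `readBratsCase()` (suffix
convention `*_t1/_t1ce/_flair/_t2/_seg.nii.gz`) and preprocessed with
`sliceDataset()` — middle 144 slices, 224×224 center crop, label
remapping, per-slice z-scoring. A thin command-line wrapper with verbs
`simulate`, `train`, `predict`, `evaluate`, `count-params` and
`export-attention` is installed at `inst/cli/hafnet.R`.

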