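---
title: "Methods: a sliding-window transformer U-Net for CT slice segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a sliding-window transformer U-Net for CT slice segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(swunet)
```

## The model

`swunet` implements a hybrid CNN / vision-transformer encoder–decoder for
2-D semantic segmentation of single-channel CT slices, aimed at small
lesions (lung nodules, liver and kidney tumors) whose segmentation benefits
from long-range context that plain convolutions, with their local inductive
bias, cannot capture.

A `1 × 128 × 128` slice is encoded by a small U-Net-style CNN: two 3×3
convolutions per level, stride-2 convolutional downsampling between levels,
channel widths doubling from 16 (16 → 32 → 64). With the default two
downsamplings the bottom feature map is `64 × 32 × 32`. A 1×1 convolution
expands the channels to the token dimension `d = 256` and the spatial dims
are flattened (row-major) into a sequence of `N = 32 × 32 = 1024` tokens.

At the bottleneck sits a single **sliding-window transformer block**: with
residual connections throughout, layer norm + windowed multi-head
self-attention on regular non-overlapping `4 × 4` windows; layer norm +
feed-forward; layer norm + the same attention on windows displaced by half
a window (realized as a cyclic shift of the features by 2 tokens up-left,
with additive masks, below); layer norm + feed-forward; and a final layer
norm + global multi-head self-attention over all `N` tokens that
consolidates information across windows. Two convolutions contract the
tokens back to the `64 × 32 × 32` bottleneck shape, and the decoder mirrors
the encoder with stride-2 transposed 3×3 convolutions, concatenating the
encoder skip features at each level, ending in a 1×1 convolution to
per-pixel class logits.

### Widened windowed attention

Depth is traded for width: instead of stacking transformer blocks, the
query/key projections of the windowed stages are widened to
`d_m = E·d` with widening rate `E = 2` while the value projection keeps
dimension `d`. Per window with tokens `x ∈ R^{M²×d}`,

```
Q = x Wq,  K = x Wk  (d × d_m),   V = x Wv  (d × d)
Attention(Q, K, V) = Softmax(Q Kᵀ / sqrt(d_m / h) + B + mask) V
```

with `h = 4` heads and a learnable relative position bias `B ∈ R^{M²×M²}`
per head. The heads' outputs are concatenated, giving back dimension `d`.

Windowing is what makes the block affordable. For an `H × W` map with `C`
channels, global attention costs `4HWC² + 2H²W²C` operations while windowed
attention costs `4HWC² + 2M²HWC` — linear instead of quadratic in the token
count. `attention_cost()` evaluates both exactly; at the operating point
(`H = W = 32`, `C = 256`, `M = 4`) the counts are 805,306,368 versus
276,824,064.

### Cyclic shift and the three masks

Shifting the windows by `s = M/2` would leave partial windows at two edges.
Instead the feature map is rolled up-left by `s` (wrapping at the borders),
which keeps the window count constant but places tokens whose original
positions were on opposite borders into the same window. Attention between
such non-adjacent tokens is meaningless, so each window receives an
additive mask, `−10⁹` on forbidden pairs and `0` elsewhere, applied before
the softmax. On a multi-window grid exactly three distinct non-trivial
patterns arise — right-edge windows (column wrap), bottom-edge windows (row
wrap) and the corner window (both) — which `build_shift_masks()` constructs
and counts. A finite `−10⁹` is used rather than `−Inf`: it drives the
post-softmax weight below `10⁻⁶` (verified by perturbation tests) while
keeping gradients defined.

## Losses and metrics

Training minimizes `L = α·L_Dice + β·L_Focal` with `α = 0.8`, `β = 0.2`:

* soft Dice, `1 − (2Σyy′ + ε)/(Σy + Σy′ + ε)`, with `ε = 10⁻⁵`; the
  empty-vs-empty case is exactly 0 loss (and the Dice *coefficient* of two
  empty masks is defined as 1);
* focal loss, `Σ −y(1−y′)^γ log y′ − (1−y)y′^γ log(1−y′)`, summed over
  pixels with `γ = 2` (a standard choice; the loss collapses to plain
  cross-entropy at `γ = 0`) and probabilities clipped at `10⁻⁷`.

For three-class (organ + tumor) data both terms are applied one-vs-rest per
foreground class (Dice averaged, focal summed), which reduces to the binary
form for two classes.

Evaluation reports per-class pixel accuracy, Dice `2TP/(2TP+FP+FN)`,
sensitivity, specificity, and the 95th-percentile Hausdorff distance. H95
is computed per direction as the 95th percentile of each point's minimum
distance to the other set, then the maximum over the two directions; the
percentile-100 case is the classical Hausdorff maximum. `full_report()`
measures it between class *boundary* pixels (4-neighbourhood), in pixel
units. Degenerate cases — an empty prediction or reference — are surfaced
as `NA` with a logged count, never silently zeroed.

## Preprocessing

Raw volumes (MetaImage `.mhd/.raw` or NIfTI) are handled as follows:
world-coordinate lesion annotations (`seriesuid, coordX, coordY, coordZ,
diameter_mm`) are rasterized as spheres of the annotated diameter using the
voxel spacing (voxel = (world − origin)/spacing, 0-based, no axis flips);
every axial slice intersecting the lesion becomes one training slice,
cropped to `128 × 128` around the in-slice lesion centroid with the window
clamped (not padded) at image borders; each cropped image is MinMax
normalized, `(x − min)/(max − min)`, into `[0, 1]` (a constant image maps
to zeros — the 0/0 case — preserving the range contract; no HU clipping is
applied before normalization). Larger/smaller sources are resampled
bilinearly (nearest-neighbour for label masks). Cases are split
80/10/10 into train/validation/test by a seeded shuffle, sizes by floor
with the remainder to train.

## Synthetic phantoms

The phantom generator provides data with the structure the pipeline
assumes, so everything — including desk-scale training — runs without any
download. Binary phantoms place 1–2 bright elliptical lesions (Gaussian
intensity profile, semi-axes 3–10 px, random orientation and 0.6–1 aspect)
on a smoothly textured background (Gaussian-smoothed noise, amplitude 0.05
around gray level 0.4); the mask is the profile's half-maximum support,
giving non-trivial boundaries for the Hausdorff metric. Lesion contrast is
0.5 with additive noise of sd 0.08 (truncated at ±2 sd so the final MinMax
stretch stays stable). Three-class phantoms draw one large elliptical
"organ" (semi-axis about a quarter of the image) containing a much smaller
circular "tumor" (15–30 % of the organ's minor semi-axis, hence under 15 %
of its area by construction), emulating the organ/tumor size imbalance of
liver and kidney tumor data. Everything is deterministic under the spec
seed.

What the phantoms do *not* emulate: CT noise statistics, anatomy,
Hounsfield calibration, inter-slice correlation, or ambiguous lesion
boundaries. Passing desk-scale tests therefore demonstrates that the
implementation is correct and trainable, not that the architecture reaches
any particular accuracy on real CT data.

## Training protocol and numerical choices

The full-scale protocol mirrors common practice for this model family:
Adam (β₁ = 0.9, β₂ = 0.999, defaults left unstated by the source protocol)
with learning rate `10⁻⁵`, batch 48, up to 100 epochs with best-checkpoint
selection on validation loss and early-stopping patience 15 ("100 rounds
with no decrease" is read as an epoch cap with checkpointing). The batch
size auto-shrinks, loudly, when the dataset is smaller than a batch.

Desk-scale runs use the same code path with different hyperparameters:
the overfitting sanity check trains the *default* model on 8 phantoms with
lr `10⁻³` decayed by 0.97 per epoch, batch 1 (more optimizer updates per
pass at fixed compute), at most 60 epochs, stopping once a confirming
forward pass puts training Dice above 0.96. At `10⁻⁵` a desk-scale run
cannot leave the initialization basin in minutes; raising the rate is the
standard adjustment for an overfitting test and does not touch the model,
data, seed or the 0.95 acceptance threshold. Ablation and pipeline tests run a reduced configuration
(input 32, widths from 4, `d = 32`) for seconds-scale turnaround; the
methods are size-agnostic.

Other numerical choices: attention scores are scaled by
`1/sqrt(per-head key dim)` (the conventional scaled dot product; the
source's divisor is typeset ambiguously); `B` is a free `M²×M²` table per
head (the literal reading) rather than a `(2M−1)²` relative-offset table;
the feed-forward sublayers are two affine maps with hidden width `4d` and
exact GELU (`x·Φ(x)`); layer norm uses `ε = 10⁻⁵`; weights initialize
truncated-normal (sd 0.02) for attention/affine arrays and fan-in-scaled
normal for convolutions, with zero biases and zero `B`; the transposed
convolution is realized as stride-2 zero-stuffing followed by a 3×3
convolution (an exact transposed convolution with output size `2n`);
downsampling is a stride-2 convolution (chosen over pooling where the
source mentions both); skip fusion is channel concatenation followed by
3×3 convolutions; the decoder mirrors encoder widths (64 → 32 → 16). The
encoder depth defaults to 2 because the stated token grid (`N = 32 × 32`
from a 128 input) and the downsampling ablation's optimum both imply two
halvings; depths 1–3 remain configurable for the ablation preset.

The whole forward *and* backward pass is implemented natively (im2col +
GEMM convolutions through two small C++ kernels, BLAS matrix products,
hand-derived gradients, Adam in R) and is verified against central finite
differences end to end at desk scale (worst relative error ~10⁻⁷ away
from ReLU kinks).

## Parameter and FLOP accounting

`count_parameters()` counts every trainable scalar of an instantiated
model; the default configuration has about 2.2M parameters, comfortably
inside the 32M budget quoted for this architecture class (the quoted figure
is treated as an upper bound — it is not derivable from the stated
dimensions, and a smaller model only strengthens the lightweightness
claim). `estimate_flops()` reports analytic per-stage multiply–accumulate
counts (1 MAC = 1 FLOP unit), with the attention stages delegated verbatim
to `attention_cost()`; published FLOP totals for comparable models are not
used as targets because their counting conventions are unknown.

## Known limitations

Single transformer block only (no hierarchical multi-resolution stages or
patch merging); 2-D slices only; no pretrained weights, deep supervision,
GPU path or DICOM series assembly; H95 in pixel units (not mm); CPU
double-precision throughput bounds practical training to desk scale.
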