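---
title: "Double-branch multi-scale segmentation of street trees: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-branch multi-scale segmentation of street trees: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Street trees — roadside canopies planted along traffic corridors — appear in
high-resolution satellite imagery at strongly varying scales: dense rows of
mature crowns tens of pixels across next to isolated young trees only a few
pixels wide. Purely convolutional encoders, with their bounded receptive
fields, tend to miss one end of that size range; purely transformer encoders
tend to miss the other. A second difficulty is radiometric: acquisition
time and illumination shift the brightness of the same canopy between
scenes, while the normalized difference vegetation index (NDVI), bounded in
[-1, 1], is far more stable — but NDVI alone cannot separate street trees
from lawns or other vegetation.

`dbmsc` implements a double-branch encoder–decoder that addresses both
points: RGB and NDVI are encoded in separate branches (their value ranges
and information content differ), each branch stacks *multi-scale contextual*
(MSC) blocks that fuse a dilated-convolution local path with a
patch-transformer global path, and the decoder merges the two pyramids with
a channel attention gate before a single-channel sigmoid head.

## The architecture

**Encoder.** Each branch runs `n_stages` stages (default 5). The raw input
`A1` (RGB) or `B1` (NDVI) is repeatedly 2x2 average-pooled to form the stage
context inputs `A_i`; the previous stage's output feature is 2x2 max-pooled.
Stage 1 consumes the raw input on both paths:

    FA_1 = msc(A_1, A_1),    FA_i = msc(A_i, maxpool(FA_{i-1})), i = 2..n

**MSC block.** The *global path* cuts the pooled image into `p x p` patches
(default `p = 16`), linearly projects each flattened patch to a `D = p^2`
token (default 256), adds a learnable positional embedding initialised to
zeros, and runs a stack of transformer blocks (default depth 6):
single-head scaled dot-product attention `alpha = softmax(q k' / sqrt(d))`,
`y = alpha v`, with post-norm ordering (attention, residual, LayerNorm,
2-layer GELU MLP, residual, LayerNorm). The final token matrix is reshaped
*flat* back to image geometry: each token's `D = p^2` values fill its source
patch in raster order. Because `D = p^2`, the token count times `D` equals
`H x W` exactly at every stage, so the global map `F0` is a single-channel
image of the stage's size. This constraint (`embed_dim = patch_size^2`) is
enforced at configuration time; it is the only reading under which the
reshape is dimensionally exact, and it also holds at reduced test scales
(`p = 4, D = 16` on 64 px tiles).

The *local path* applies four parallel 3x3 stride-1 convolutions with
dilations 1, 2, 3 and 5 ('same' padding, `w` channels each, receptive
offsets up to +/-5 pixels) concatenated by channel, plus a 1x1 convolution
to `4w` channels added elementwise — well-formed only because the concat and
the 1x1 branch have identical channel counts, which the model asserts at
build time. The block output is `concat(local, F0)`: `4w + 1` channels.

Branch widths are an explicit per-stage schedule (default 8, 16, 32, 64,
64) rather than a strict halving rule: halving is non-integral for the
3-channel RGB and 1-channel NDVI inputs and for the odd channel counts
created by the `+1` global channel. The defaults keep `w` close to half the
incoming channel count where that is feasible.

**Decoder.** `Q_5 = [FA_5, FB_5]`; then for `i = 4..1`:
`P_i = CAM(ReLU(conv3x3(upsample2x(Q_{i+1}))))` and
`Q_i = [FA_i, P_i, FB_i]`; a final 3x3 convolution reduces `Q_1` to one
channel. The operation order (upsample, convolution, ReLU, gate) follows
the architecture's stated decoding sequence. Decoder convolution widths
default to the matching encoder stage's channel count (`4w_i + 1`), keeping
the three concatenands of `Q_i` balanced. The channel attention gate (CAM)
pools each channel to its spatial mean and maximum, passes both vectors
through one *shared* two-layer ReLU MLP (hidden width `C/r`, `r = 8`,
clamped to at least 1 with a warning when `C < r`), sums, applies a sigmoid
and rescales the channels; since the scales lie in (0, 1) the gate can only
attenuate, never amplify.

**Head and loss.** One output channel through a sigmoid, trained with mean
binary cross-entropy (predictions clamped to `[1e-7, 1 - 1e-7]`), binarised
at 0.5 for evaluation. The binary form of the loss is matched by the
single-channel head; a two-channel softmax reading would be redundant for a
two-class problem.

## Training protocol

Adam with `beta1 = 0.9`, `beta2 = 0.999`, initial learning rate `1e-3`,
batch size 5, 100 epochs by default. "Adaptive learning rate" is
implemented as reduce-on-plateau — halve the rate after 10 epochs without
validation-loss improvement — since no specific schedule is prescribed by
the method; the validation split drives best-epoch checkpointing (with no
validation split the training loss is monitored and the final weights are
kept). Repetition (`n_repeats`) reruns training under independent seeds for
mean/sd reporting; the default is a single run at desk scale. Everything —
initialisation, batch order, augmentation — derives from one integer seed,
so a run is bit-reproducible.

Initialisation: He scaling for convolutions and MLPs feeding ReLU/GELU,
Glorot for projections, zeros for positional embeddings and biases,
LayerNorm gain 1 / bias 0. Positional embeddings are zero-initialised but
remain learnable (the standard reading of an "initialised" parameter).

## Augmentation

Random integer shifts (up to 10% of the tile side; reflected borders for
RGB/NDVI, zero fill for the mask), random rotations, horizontal/vertical
flips, and RGB-only brightness jitter of up to +/-10%, clipped back to
[0, 1]. Geometric transforms are applied identically to RGB, NDVI and mask;
brightness never touches NDVI or the mask. Rotations default to multiples
of 90 degrees: binary masks survive them without interpolation artifacts.
An arbitrary-angle mode (nearest-neighbour) exists behind a flag for users
who want denser orientation coverage and accept resampling noise. Shift
magnitude, rotation policy and padding are package choices; only the
brightness bound and the transform families themselves are inherited from
the method.

## The synthetic scene generator

The generator emulates the statistical structure of the street-tree task so
the whole pipeline is testable without satellite data: a low-NDVI gray road
corridor; canopies as anti-aliased ellipses placed within a buffer of the
corridor, with radii drawn from a bimodal mixture (defaults 2–6 px and
12–40 px, mixing weight 0.3 for the large regime — spanning more than a
five-fold scale ratio, since no quantitative size distribution is available
for the two regimes); about 11% of tiles empty; grass distractors that
*share the tree NDVI distribution* but differ in RGB, placed away from the
corridor — deliberately making NDVI thresholding insufficient so the
double-branch fusion is actually exercised; a per-tile illumination
multiplier in [0.85, 1.15] emulating acquisition-time brightness variation
(the motivation for the NDVI branch); Gaussian pixel noise (RGB sd 0.03,
NDVI sd 0.02). Masks binarise the anti-aliased coverage at 0.5 because the
evaluation statistics are defined on hard labels. Canopy placement stops at
55% tile coverage so a tile is never flooded.

What the generator does **not** model: building shadows (a known failure
mode of the method on real imagery), multi-season spectra, sensor PSF and
pan-sharpening artifacts, georeferencing. Tests passing on these scenes
demonstrate that the architecture, gradients, training loop and metrics are
correct and that the network can learn the multi-scale street-tree
abstraction; they do not certify accuracy on real satellite data.

## Numerical and design choices

* **Hand-written training engine.** No deep-learning framework is used: the
  forward pass, backpropagation and Adam are implemented in R with small
  C++ kernels (im2col/col2im) and BLAS matrix products. Every layer's
  gradient is verified against central finite differences in the test
  suite, and a whole-network check runs on a 3-stage model.
* **Single-token attention stages.** At the top of the pyramid the context
  input is exactly one patch (e.g. 16 px at `p = 16`), so attention reduces
  to the identity over one token and the gradients of `W_Q`/`W_K` at that
  stage are *structurally* zero (softmax of a single logit is constant).
  The gradient-flow test asserts nonzero gradient norms for every tensor
  except these, and asserts exact zeros for them.
* **Micro-averaged evaluation.** Confusion counts are summed over all tiles
  before scoring; per-tile macro averages are available behind a flag. The
  chance-agreement term of Cohen's kappa is computed on proportions
  (counts/total), the only form in which the products are well-scaled.
  "mIoU" is reported as foreground IoU, with a separate two-class macro IoU
  to resolve the naming ambiguity.
* **Degenerate tiles.** Empty-mask/empty-prediction tiles define F1 and IoU
  as 1 and kappa as 0, with explicit flags, instead of NaN.
* **NDVI persistence.** NDVI is stored as float NPY (or read from float
  TIFF), never quantised to 8 bits: the [-1, 1] precision is the NDVI
  branch's signal.
* **Tiled inference.** Large rasters are partitioned on a grid of stride
  `tile - overlap`; edge tiles are reflect-padded to full size and cropped
  back; overlapping predictions are averaged in probability space before
  thresholding.

## Problem sizes used in tests and the acceptance script

The packaged experiments run at desk scale, chosen so the full pipeline is
exercised end to end on a single CPU: 64 px tiles with canopy radii scaled
to 1.5–3 px and 6–12 px (the same two-regime structure), and a reduced
architecture (`p = 4`, `D = 16`, depth 2, widths 4/8/8/8/8). The
trainability check trains this model for 200 optimisation steps (50 epochs
of batch 2) on 8 tiles and reaches training foreground IoU above 0.9; the
generalisation run trains on 48 tiles for 12 epochs and evaluates on a
held-out test split. Architecture contracts (stage sizes, token counts,
channel arithmetic, value conservation of the global reshape) are verified
at the full default geometry: 256 px tiles, `p = 16`, `D = 256`, depth 6.

## Known limitations

* CPU training at the full 256 px scale is possible but slow; the package
  targets method verification and desk-scale experimentation, not
  production training on large datasets.
* Shadow-covered canopies, the documented weak point of the approach on
  real imagery, are neither modelled by the generator nor addressed by the
  architecture.
* The decoder width schedule and transformer MLP width are declared
  defaults (the method's public description does not pin them); both are
  configurable.
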