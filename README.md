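# dbmsc

Semantic segmentation of **street trees** from paired RGB + NDVI raster
tiles with a double-branch, multi-scale contextual encoder–decoder network —
implemented entirely in R (hand-written forward/backward passes and Adam,
with small C++ kernels for the convolutions), for researchers in urban
green-space monitoring and remote-sensing image analysis who want a fully
inspectable, CPU-reproducible implementation of this architecture.

## The model

Street trees appear in high-resolution imagery at widely different sizes,
and their RGB brightness varies with acquisition conditions while NDVI
(bounded in [-1, 1]) is more stable but not specific to trees. The network
therefore:

* encodes RGB (`A`) and NDVI (`B`) in **two separate branches**, five stages
  each, with 2x2 average pooling of the raw input and 2x2 max pooling of the
  features between stages:

  `FA_1 = msc(A_1, A_1)`, `FA_i = msc(A_i, maxpool(FA_{i-1}))`;

* builds each stage from an **MSC block** that concatenates a *local* path —
  four parallel 3x3 dilated convolutions (dilations 1, 2, 3, 5; `w` channels
  each) plus an elementwise 1x1 branch — with a *global* path: `p x p` patch
  embedding into `D = p^2` tokens, a stack of transformer blocks
  (`alpha = softmax(q k' / sqrt(d))`, `y = alpha v`, post-norm residual
  MLP), and a flat reshape of the tokens back to a single-channel map `F0`,
  giving `4w + 1` output channels;

* decodes with `Q_5 = [FA_5, FB_5]`,
  `P_i = CAM(ReLU(conv3x3(upsample2x(Q_{i+1}))))`,
  `Q_i = [FA_i, P_i, FB_i]`, where **CAM** is a channel-attention gate
  `sigma(MLP(avgpool(F)) + MLP(maxpool(F)))` with one shared MLP;

* predicts through a single-channel sigmoid head trained with mean binary
  cross-entropy, and is evaluated by overall accuracy, F1, foreground IoU
  and Cohen's kappa on micro-averaged pixel confusion counts.

A seeded synthetic scene generator (road corridor, bimodal canopy sizes,
high-NDVI grass distractors, illumination jitter, ~11% empty tiles) stands
in for satellite data so every component is testable end to end.

## Worked example

```r
library(dbmsc)

# 1. A synthetic street-scene dataset: 30 tiles of 64 px, 8:1:1 split
params <- scene_params(tile_size = 64, small_radius_range = c(1.5, 3),
                       large_radius_range = c(6, 12))
manifest <- generate_dataset(params, n_tiles = 30, out_dir = "scenes",
                             seed = 1)

# 2. A reduced double-branch model (p = 4, D = 16, depth 2)
cfg <- model_config(n_stages = 5,
                    msc = msc_config(patch_size = 4, embed_dim = 16,
                                     depth = 2, widths = c(4, 8, 8, 8, 8)),
                    tile_size = 64)
fit <- train_model(manifest, cfg,
                   train_config(epochs = 8, batch_size = 5, seed = 2,
                                augment = augment_spec()),
                   verbose = TRUE)

# 3. Evaluation on the held-out test split (micro-averaged counts)
report <- evaluate_model(fit, manifest, split = "test")
str(report$scores)
```

This prints one log line per epoch and ends with the held-out scores
(2-3 minutes on one CPU):

```
epoch=6 train_loss=0.1229 val_loss=0.1882 val_oa=0.9240 lr=0.001
epoch=7 train_loss=0.1213 val_loss=0.1992 val_oa=0.9262 lr=0.001
epoch=8 train_loss=0.1176 val_loss=0.1843 val_oa=0.9345 lr=0.001
List of 8
 $ oa        : num 0.922
 $ f1        : num 0.791
 $ iou       : num 0.654
 $ macro_iou : num 0.781
 $ kappa     : num 0.744
 $ p0        : num 0.922
 $ pe        : num 0.694
 $ degenerate: chr(0)
```

`oa` is the fraction of correctly labelled pixels; `iou` is the foreground
(street-tree) intersection-over-union, the quantity usually reported as
"mIoU" in two-class tree segmentation; `macro_iou` averages foreground and
background IoU; `kappa` is chance-corrected agreement. Eight epochs on 24
small training tiles already separate canopy from road, background and
high-NDVI grass distractors; longer training tightens the boundaries (see
`scripts/acceptance.R`, which reaches test IoU ≈ 0.88 after 12 epochs on 48
tiles).

Inference on rasters larger than one tile uses `predict_tiles(fit, rgb,
ndvi, tile = 64, overlap = 16)`, which stitches tile predictions and
averages probabilities in the overlaps. A thin command-line front end with
`generate` / `train` / `eval` / `predict` subcommands is installed at
`inst/cli/dbmsc`.

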