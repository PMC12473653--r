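---
title: "Methods: losses, attention, content-aware fill and accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: losses, attention, content-aware fill and accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracdet)
```

`fracdet` provides the numerical building blocks of a single-class
fracture detector for radiographs: dataset handling, a synthetic phantom
generator, content-aware augmentation, a multi-scale attention block, the
SIoU/Focal-SIoU loss family, detection metrics, and exact parameter/FLOP
accounting for the nano detector architecture the blocks target. This
vignette walks through the methods and their conventions.

## Synthetic phantoms and dataset layout

The phantom generator draws bone-like capsules on a dark background,
interrupts them with darker hairline fractures, and records the exact
bounding box of each fracture. Everything is deterministic given a seed.

```{r phantom}
cfg <- phantom_config(image_size = 96, bone_halfwidth = c(4, 7))
ph <- generate_phantom(cfg, seed = 42)
dim(ph$image)
ph$boxes
```

Datasets use the YOLO text layout (`images/*.png`, `labels/*.txt` with
normalized `class cx cy w h` rows) and deterministic 7:2:1 splitting. The
test partition takes `floor(0.1 n)` items, the training partition
`round(0.7 n)`, and validation the remainder:

```{r split}
split_dataset(sprintf("x%05d", seq_len(14267)), c(7, 2, 1), seed = 1)$sizes
```

## Content-aware fill augmentation

Rotations and translations vacate part of the frame; the warp marks those
pixels with exact zeros. The fill pipeline detects them
(`blank_mask()`), infers a fill colour from the non-blank border
(`edge_color()`), covers the hole with that colour (`coarse_fill()`), and
then solves a Poisson (Laplace) equation over the hole with Dirichlet
boundary values from the surrounding image (`poisson_refine()`), so the
fill blends smoothly instead of leaving a flat patch. On a linear
intensity ramp the harmonic extension is the ramp itself:

```{r poisson}
h <- 24; w <- 24
ramp <- outer(seq_len(h), seq_len(w), function(i, j) 40 + 4 * j)
img <- array(rep(ramp, 3), c(h, w, 3))
mask <- matrix(0, h, w); mask[8:16, 8:16] <- 1
refined <- poisson_refine(coarse_fill(img, mask, rep(mean(ramp), 3)), mask)
max(abs(refined - img))
```

`augment_image()` chains the geometric transform (boxes are mapped
through the same affine matrix) with the fill, and `augment_dataset()`
applies it to a whole dataset with per-image derived seeds.

## The Bone-MSCA attention block

`bone_msca()` builds a residual attention block operating on
`(B, C, H, W)` feature maps:

1. **Directional fusion** — depthwise 21×1 and 1×21 strip convolutions
   (long, thin bone shafts) plus two depthwise 7×7 dilated convolutions
   (dilations 2 and 3; oblique structure), summed.
2. **Deformable stage** — a full 3×3 convolution predicts 18 offset
   channels (a `(dy, dx)` pair for each of the 9 taps, shared by all
   channels), then a depthwise deformable 3×3 convolution samples the
   fused features bilinearly at the offset positions. Zero offsets
   reduce it exactly to a plain convolution.
3. **Sobel edge gate** — fixed (non-trainable) Sobel kernels give
   `sigmoid(|G_x| + |G_y|)`; features are multiplied by one plus this
   gate, so flat regions pass with factor 1.5 and edges are amplified
   towards 2.
4. **Squeeze-and-excitation** — channel recalibration with reduction 4.

The block output is `X + refined(X)`. Its closed-form parameter count is
checked against introspection of an instantiated block:

```{r msca}
bone_msca_parameter_count(256)
blk <- bone_msca(bone_msca_config(8), seed = 1)
bone_msca_num_weights(blk) == bone_msca_parameter_count(8)
```

## SIoU and Focal-SIoU losses

For a predicted and a ground-truth box the SIoU loss is
`1 - IoU + (Delta + Omega) / 2` with

* **angle cost** `Lambda = 1 - 2 sin^2(arcsin(sin alpha) - pi/4)` where
  `sin alpha` is the vertical center offset over the Euclidean center
  distance — 0 when the centers are axis-aligned, 1 at 45°;
* **distance cost** `Delta = sum_t (1 - exp(-(2 - Lambda) rho_t))` with
  `rho_t` the squared center offsets normalized by the enclosing box
  (`distance_cost(..., paper_literal = TRUE)` switches to the unsquared
  variant);
* **shape cost** `Omega = sum_t (1 - exp(-varpi_t))^theta` with relative
  width/height differences.

The focal variant multiplies by `-(1 - IoU)^tau log(IoU)`, concentrating
gradient on hard, low-overlap boxes. Analytic gradients
(`box_loss_grad()`) are provided for `iou`, `siou` and `focal_siou` and
match finite differences:

```{r loss}
p <- c(9, 11, 30, 28); g <- c(10, 10, 30, 30)
box_loss(matrix(p, 1), matrix(g, 1), loss_config("focal_siou"))
box_loss_grad(p, g, loss_config("focal_siou"))$grad
```

## Metrics

Detections are matched greedily per image in order of decreasing
confidence (one-to-one, IoU at or above the threshold). Pooled outcomes
give the all-point interpolated precision-recall curve; its area is the
average precision, equal to mAP50 for this single-class problem.

```{r metrics}
precision_recall_f1(9, 1, 3)
pr_curve(c(TRUE, FALSE, TRUE), 3)$ap
```

## Architecture accounting

`build_model()` enumerates every convolution of the nano detector
(backbone, neck and decoupled head), which yields exact parameter counts
and multiply-accumulate counts at any input size. Reported figures follow
the deployment convention: parameters of the *fused* model (batch-norm
folded into the convolutions) and GFLOPs as twice the MAC count at
640×640. The `bf` variant adds one Bone-MSCA block at the backbone
terminus and records Focal-SIoU as its box loss.

```{r model}
model_info(build_model("baseline"))
model_info(build_model("bf"))
```

The package contains no neural-network training engine: `smoke_train()`
documents that boundary by raising an error. The assembled architecture
description, loss, augmentation and metrics are designed to be paired
with an external training framework, with `evaluate_detections()` scoring
the resulting predictions.
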