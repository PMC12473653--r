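# fracdet

Building blocks for single-class fracture detection in radiographs,
implemented in pure R:

* **Dataset I/O** — YOLO text-format reading/writing with strict label
  validation, PNG round-trips, and deterministic 7:2:1 train/val/test
  splitting (`floor`/`round`/remainder convention).
* **Synthetic phantoms** — a seeded generator of bone-like capsule images
  with hairline fractures and exact bounding-box labels, for fixtures and
  pipeline tests.
* **Content-aware augmentation** — rotation/translation/flips with label
  propagation; vacated frame regions are detected, filled from border
  statistics and refined by Poisson (gradient-domain) blending so no
  black padding wedges remain.
* **Bone-MSCA attention block** — directional strip convolutions, dilated
  convolutions, a depthwise deformable 3×3 stage with predicted offsets,
  a fixed Sobel edge gate and squeeze-and-excitation recalibration, as a
  residual block with exact parameter accounting.
* **Losses** — the IoU/CIoU/SIoU family with Focal weighting and analytic
  gradients (`iou`, `siou`, `focal_siou`), verified against finite
  differences and an independent transcription of the equations.
* **Metrics** — greedy confidence-ordered matching,
  precision/recall/F1, all-point interpolated AP and mAP50.
* **Architecture accounting** — an exact per-convolution description of
  the nano detector (and its Bone-MSCA variant) giving parameter counts
  (as trained and deployed/fused) and GFLOPs at any input size.

## Worked example

```r
library(fracdet)

## 1. generate a small synthetic dataset
cfg <- phantom_config(image_size = 96, bone_halfwidth = c(4, 7))
generate_phantom_dataset(cfg, 20, "phantoms", seed = 1)

## 2. split and augment it
items <- list.files("phantoms/images")
split_dataset(items, c(7, 2, 1), seed = 1)$sizes
augment_dataset("phantoms", "phantoms_aug", per_image = 2, seed = 2)

## 3. inspect the detector variants the components target
model_info(build_model("baseline"))  # 2.58M parameters, 6.3 GFLOPs
model_info(build_model("bf"))        # 2.70M parameters, 6.4 GFLOPs

## 4. compute a loss and its gradient
p <- c(9, 11, 30, 28); g <- c(10, 10, 30, 30)
box_loss(matrix(p, 1), matrix(g, 1), loss_config("focal_siou"))
box_loss_grad(p, g, loss_config("focal_siou"))$grad

## 5. score detections
truth <- list(data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10))
pred <- list(data.frame(x1 = 1, y1 = 0, x2 = 11, y2 = 10,
                        confidence = 0.9))
evaluate_detections(pred, truth)$map50
```

## Command line

A thin CLI wraps the main entry points:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fracdet.R", package = "fracdet"))')" \
  synth --out phantoms --n 20 --seed 1 --split
# also: augment, eval, info, train
```

## Scope

The package deliberately contains no neural-network training engine;
`smoke_train()` raises an informative error. Assemble the described
architecture in a detection framework, train it there, and evaluate the
predictions with `evaluate_detections()`.

## Tests

```r
testthat::test_dir("tests/testthat", package = "fracdet",
                   load_package = "installed")
```

The acceptance report can be regenerated with

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
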