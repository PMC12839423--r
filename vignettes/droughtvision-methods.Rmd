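---
title: "Methods: tiled detection, bio-inspired blocks and synthetic Fv/Fm scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiled detection, bio-inspired blocks and synthetic Fv/Fm scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtvision)
```

## The problem

Drought stress in plant seedlings shows up early in chlorophyll-fluorescence
imagery: the maximum photochemical quantum efficiency of photosystem II
(Fv/Fm) declines with water deficit well before gross morphology changes.
Grading drought from Fv/Fm maps can be posed as object detection: find every
seedling in the image and assign it one of four severity classes defined by
soil relative humidity intervals (level 1, no drought, at W >= 60%; level 2
at 50 <= W < 60; level 3 at 40 <= W < 50; level 4 at 30 <= W < 40). This
package implements the computational machinery of a compound-eye-inspired
detection pipeline for this task: mosaic-tiled inference with exact label
remapping, two feature-map blocks (multi-scale linear attention and
CMUNeXt), an auxiliary-box regression loss, a detection metric suite, a
layer-table model assembly with parameter accounting, and a synthetic scene
generator that stands in for imaging data that is not publicly deposited.

## Mosaic tiling (CEAC)

An apposition compound eye samples many slightly offset directions in
parallel and integrates them downstream. The computational analogue batches
`x^2` images into one square, gap-free mosaic so the detector processes them
in a single forward pass, then maps the detections back into each
sub-image's own normalized coordinate frame.

The geometry is exact, not approximate. Composing maps a tile-frame label
`(cx, cy, w, h)` into the mosaic by denormalizing with the tile dimensions,
offsetting by the tile origin `(col * tile_w, row * tile_h)`, and
renormalizing by the canvas; splitting inverts this. Round-tripping is
identity to floating-point precision, which the test suite checks over a
thousand random scenes.

Three choices the geometry itself does not dictate:

* **Straddle rule.** A detection is assigned to the tile containing its
  center (the YOLO label semantics), clipped to that tile, and dropped when
  the clipped area falls below 10% of the original (configurable
  `retention`). Boxes that straddle a seam are genuinely ambiguous; clipping
  to the center tile keeps the per-tile frames self-consistent.
* **Seam tie-break.** Tiles are half-open intervals `[start, start + size)`,
  so a center exactly on a seam belongs to the right/bottom neighbour;
  deterministic and consistent with pixel indexing.
* **Training-time use.** During training the wrapper composes `x^2`
  randomly sampled training images per step, with classes mixing freely;
  nothing in the method requires same-grade mosaics, and random mixing is
  the less restrictive default.

The grid defaults to `x = 3` (nine tiles), the published speed/accuracy
trade-off point; grids 1-4 are supported.

## Multi-scale linear attention (MSLA)

MSLA models the "multi-scale parallelism - global modulation - long-range
integration" motif of primate vision. The input of `C` channels is split
into four blocks of `C/4`. Block `i` passes through a same-padded depthwise
convolution of kernel 3, 5, 7 or 9 with a residual connection and ReLU:
`ReLU(dwconv_k(X_i) + X_i)`. Each activated block is flattened to one token
per spatial position and run through linear attention: with projections
`Q = T W_q`, `K = T W_k`, `V = T W_v`, the output is
`phi_q(Q) (phi_k(K)^T V)` where `phi_q` is a row-wise softmax and `phi_k` a
column-wise softmax. Because the context `phi_k(K)^T V` is only `d x d`, no
`N x N` attention matrix is ever formed, and the cost is linear in the token
count — the property the test suite verifies against the naive
`(phi_q(Q) phi_k(K)^T) V` order. The branch outputs, scaled by learnable
gates `w_1..w_4` (initialized to 1), are concatenated and fused by a 1x1
convolution.

Numerical choices: both softmaxes subtract the per-row/column maximum before
exponentiation and add 1e-12 to the denominators. The head count defaults to
1 per branch (head dimension `C/4`) and is configurable; nothing in the
block's definition pins it, and parameter pinning against the published
per-layer counts of the attention-bearing C3k2 rows is not attainable (see
*Parameter accounting* below).

## CMUNeXt block

The CMUNeXt block mirrors retinal wide-field lateral inhibition followed by
selective cortical convergence: a large-kernel depthwise convolution
integrates long-range spatial structure within each channel at low cost,
`f' = BN(GELU(dwconv(f) + f))`; a pointwise 1x1 convolution expands the
channels to a wider space, `f'' = BN(GELU(pw_{C->E}(f')))`; a second
pointwise convolution compresses back, `f_out = BN(GELU(pw_{E->C}(f'')))`.
The two channel-mixing stages are full 1x1 convolutions: where prose
descriptions of the block call them "depthwise", the defining equations
write pointwise convolutions, and the equations win. Defaults are kernel
7x7 and expansion `E = 4C`, the cited CMUNeXt design; `depth` stacks units.

## Inner-CIoU loss

Bounding-box regression uses the CIoU loss completed with the Inner-IoU
auxiliary-box mechanism. Both the predicted and ground-truth boxes are
rescaled about their own centers by a factor `ratio`; the IoU of these
auxiliary boxes replaces part of the training signal:

* `inner_box`: edges at `center ± side * ratio / 2`.
* `inner_iou`: intersection over union of the two auxiliary boxes, each
  intersection factor clamped at zero first — the raw edge formula is
  sign-unsafe and would multiply two negative extents into a spurious
  positive overlap for disjoint boxes.
* `ciou_loss`: `1 - IoU + rho^2/c^2 + alpha v`, with `v` the `4/pi^2`
  arctan aspect term and `alpha = v/((1-IoU)+v)` treated as constant with
  respect to gradients — the standard CIoU completion, adopted because the
  loss equation matches the canonical CIoU form and the weighting terms are
  otherwise undefined.
* `inner_ciou_loss` (default `variant = "additive"`):
  `L_CIoU + IoU - InnerIoU(ratio)`, exactly as the defining equation prints
  it. At `ratio = 1` the last two terms cancel algebraically. A
  `variant = "substituted"` switch instead places the auxiliary IoU inside
  the CIoU expression (`1 - InnerIoU + rho^2/c^2 + alpha v`), the form used
  in the original Inner-IoU formulation. For `ratio > 1` the additive form
  can in corner cases go slightly negative; values are reported as
  computed, never clipped.

Larger auxiliary boxes early in training enlarge the effective intersection
region in low-IoU and occluded configurations; shrinking them later sharpens
sensitivity to small localization errors. The schedule is a linear
interpolation from `r_start` to `r_end` across the training horizon. No
numeric schedule endpoints are published; the default 1.25 -> 0.75 brackets
the identity ratio symmetrically and both endpoints are configuration, not
claims.

## Metrics

Evaluation follows the standard detection protocol. Greedy matching
processes detections in decreasing confidence; a detection is a true
positive when its best IoU against an unmatched same-class ground truth in
the same image reaches the threshold (0.5 by default). Equal-confidence ties
are broken by box content (class, center, size) rather than input position,
which makes the result — including AP — invariant to detection row order; a
positional tie-break could not satisfy that invariance. Precision, recall
and F1 use the usual ratios with zero denominators mapping to 0 with a
warning. Average precision integrates the all-point-interpolated
precision-recall curve, `P_inter(r) = max { precision at recall >= r }`,
from a recall-0 anchor; mAP@50 averages classes, and mAP@50-95 additionally
averages IoU thresholds 0.50 to 0.95 in steps of 0.05. All-point (not
11-point or 101-point) interpolation is used because the defining summation
is over the observed recall points themselves.

## Model assembly and parameter accounting

The detector is assembled from a 34-row layer table (shipped as
`inst/extdata/mc_yolov13_l_layers.csv`) that mirrors the published
MC-YOLOv13-L layout: id, source layers, module name, argument vector, and
the published per-layer parameter count. A registry maps module names to
constructors; wiring follows the `from` column exactly, and a 640x640 input
yields three detection maps at strides 8/16/32 for the four drought grades.

Parameter accounting distinguishes three tiers:

1. **Derivable and pinned.** Convolution blocks follow conv-without-bias
   plus batch norm (2 trainable scalars per channel; running statistics not
   counted). This convention uniquely reproduces every printed plain-Conv
   row (464; 2,368; 9,344; 8,320; 36,992; 147,712). It also pins the
   depthwise-separable rows (depthwise stage with no bias and no norm, then
   pointwise + BN: 17,792 and 34,432), the channel-doubling downsample block
   (33,280), and the one-parameter gated fusion tunnel.
2. **Defined here, not pinned.** The base network's aggregation modules
   (HyperACE-style cross-scale aggregation, A2C2f-style residual
   aggregation, the detect head) are not defined by their printed counts
   alone; this package implements its own functionally equivalent stand-ins
   with correct shapes and wiring, documented as such.
3. **Not attainable.** The printed counts of the attention-bearing C3k2
   rows and the CMUNeXt row (1,121,792 for `[256, 256, 1]`) are not
   reproduced by any standard dimensioning of those blocks that we could
   derive arithmetically (for example, CMUNeXt with kernel 7 and `E = 4C`
   gives 539,904 with no integer expansion solving the printed value for
   one or two stacked units, with or without convolution biases). The
   defaults above are kept, and the built model's total therefore differs
   from the printed 3,477,567. The printed column itself, shipped as data,
   sums to exactly that total, which is what the table-consistency check
   asserts.

The gated fusion tunnel is `out = x1 + g * x2` with a single scalar `g`
initialized to 0 — one trainable parameter, an identity path at
initialization, and guaranteed gradient flow.

## Training engine and smoke training

No automatic-differentiation framework is assumed: every block carries a
hand-derived backward pass (im2col convolutions via BLAS matrix products
with per-offset scatter for input gradients, batch-norm and softmax
backward in closed form), verified against central finite differences in
the unit tests. The training loss combines Inner-CIoU box regression on
positive cells (gain 7.5) with binary cross-entropy classification over all
cells (gain 0.5), the published loss-gain configuration; distribution focal
loss is delegated to the surrounding framework and not re-implemented.
Target assignment is the plain anchor-free rule (scale by box size — side
under 64 px to stride 8, under 128 px to stride 16, else stride 32 — and
cell by box center).

Smoke training demonstrates optimizability at desk scale: 64 synthetic
640x640 scenes, 2 epochs, batch size 2, SGD with momentum 0.937 and weight
decay 0.001 (the published optimizer settings) at a desk-scale learning
rate of 0.005, with the auxiliary-box ratio annealed 1.25 -> 0.75 across
the run. The check asserts that the mean total loss falls from epoch 1 to
epoch 2. This is a property of the implementation (gradients are correct
and descent makes progress), not a claim about publication-scale accuracy:
full training at 500 epochs and batch 16 is out of scope.

## The synthetic scene generator

No imaging data accompanies the method, so the generator emulates what the
detector consumes: 640x640 single-channel Fv/Fm-style scenes containing
elliptical leaf blobs on a dark background. Each scene carries one drought
grade; foreground intensity is drawn around a per-grade mean (0.80, 0.68,
0.55, 0.40 for levels 1-4, with spread 0.04) — plausible Fv/Fm physiology
for healthy through severely stressed tissue, strictly decreasing with
severity, and configuration rather than a biological claim. A mild radial
falloff inside each blob imitates vein/edge attenuation. Boxes are the
tight axis-aligned extents of the rotated ellipses, and blobs are kept
fully inside the frame so every label satisfies the normalized-label
invariants.

What the generator does **not** emulate: overlapping canopies, soil and pot
background structure, sensor vignetting and exposure variation, the
continuous gradation of stress within a single plant, and the label noise
of human annotation. Passing tests therefore demonstrate the correctness of
the pipeline's geometry, losses, metrics and optimization, not field
performance on real fluorescence imagery.

The augmentation suite mirrors the published protocol: HSV perturbation
(applied to a false-color rendering of the single-channel map, then
converted back via luminance — fluorescence maps have no native hue to
jitter), mean/Gaussian/median blur, CutOut with 1-6 patches totalling 5-40%
of the image (patches are placed in disjoint grid cells so the realized
occluded fraction equals the requested one to within a pixel), the eight
D4 symmetries of the square (the only label-changing operation, exactly
invertible), and random brightness. Each augmented variant draws one
operation; whether the original protocol chained operations per image is
unstated, and one-op-per-variant keeps variants interpretable.

Dataset bookkeeping follows "first division, then enhancement": the
originals are split train/test/validation first (20% validation, remainder
8:2), then each original is expanded within its split. With 324 originals
and 12 variants per original — the unique integer consistent with the
published 2691/676/845 totals under those fractions, as the published
protocol never states the count — the splits are 207/52/65 originals and
2691/676/845 images. The manifest records every file's source scene, and a
mechanical check asserts that no source contributes to two splits. Humidity
below 30% is outside the grading scale and raises an error rather than
clamping to level 4 — silent clamping would fabricate a grade.

## Problem sizes used by the test suite

The unit tests run oracles at small sizes (feature maps up to 16x16,
token counts up to 32, box sweeps over small integer grids) where naive
reference implementations are exact and fast. The mosaic round-trip
property uses about a thousand 48-pixel scenes; dataset bookkeeping runs at
the full 324-original scale (labels and manifest only; pixel rendering is
optional and lazy). Smoke training runs the full network at 640x640 on 64
scenes for 2 epochs. These sizes are the package's chosen desk-scale study
conditions.

## Known limitations

* The built model's total parameter count intentionally differs from the
  published total (tier-2/3 modules above); per-layer pinning covers the
  derivable rows only.
* Batch normalization always uses batch statistics (training mode);
  running-average inference statistics are tracked nowhere, which is
  adequate for desk-scale training checks but not for deployment.
* The detection loss omits distribution focal loss; box quality at
  publication scale would differ.
* The CPU engine is tuned for clarity-with-reasonable-speed, not for
  large-scale training.
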