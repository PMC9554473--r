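---
title: "Counting wheat spikes with an attention-augmented one-stage detector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting wheat spikes with an attention-augmented one-stage detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spike (head) number per unit area is a primary yield component in wheat, and
counting spikes in field photographs is the bottleneck step of many
phenotyping protocols. Field imagery at heading stage is hard for detectors
for three reasons: spikes are small and dense, they occlude and cross each
other, and their color is often close to the canopy background. `spikedet`
implements a compact one-stage detector specialized for this setting —
a small CSP-Darknet backbone whose C3 blocks carry efficient channel
attention (ECA) gates, and a detection head preceded by a global attention
mechanism (GAM) at each scale — together with the loss, metrics, and data
pipeline needed to train it and to evaluate counting accuracy.

Everything is implemented in R: convolution and pooling kernels are compiled
(RcppArmadillo) and every other layer, including all hand-derived backward
passes, is plain R. The test suite validates each backward pass against
central finite differences.

## The network

The detector is the familiar three-scale single-stage layout with an input
of 640 × 640 × 3 (any multiple of 32 works):

* **Backbone** — a Focus stem (space-to-depth into 12 channels, then a 3 × 3
  convolution to 32), four downsampling stages with channel widths
  64/128/256/512, C3 blocks with repeat counts (1, 2, 3, 1), and a spatial
  pyramid pooling block (pools 5/9/13) before the last C3. Backbone C3
  blocks are replaced by ECA-C3 blocks.
* **Neck** — FPN top-down plus PAN bottom-up fusion; neck C3 blocks use one
  bottleneck and no shortcut.
* **Head** — three 1 × 1 prediction convolutions (strides 8/16/32, three
  anchors each, `3 * (5 + nc)` outputs per cell), each preceded by a GAM on
  its 128/256/512-channel input.

Every composite convolution is bias-free and followed by affine batch
normalization and a SiLU nonlinearity. These conventions are not cosmetic:
together with the repeat counts and the 0.5 hidden expansion of the C3
blocks they pin the per-layer trainable-parameter table exactly, and the
test suite asserts all 25 rows (3,520 for the stem through 8,622,262 for
the detection stage; 15,628,418 in total). `layer_param_counts()` prints
the table; the repeat counts (1, **2**, 3, 1) are load-bearing — the common
(1, 3, 3, 1) variant does not reproduce the reference counts.

### ECA

The ECA gate pools each channel to a scalar (global average pooling), runs a
weight-sharing, bias-free 1-d convolution of size *k* across the channel
axis, and multiplies the input by the sigmoid of the result. It costs
exactly *k* parameters. Two kernel policies are available:

* `fixed3` (default): *k* = 3 regardless of width. This is the convention
  consistent with the reference parameter table, where every ECA-C3 block
  costs exactly 3 parameters more than its plain C3 counterpart.
* `adaptive`: *k* = |log2(C)/γ + b/γ| rounded to the nearest odd integer
  (γ = 2, b = 1), which yields 5 for C ≥ 256. Half-integer ties (C = 128
  gives 4.0) round to the *smaller* odd number so the two policies agree at
  C = 128.

The two policies disagree for the two widest blocks; since the parameter
table arithmetic only works out with 3-tap kernels, `fixed3` is the default
and the adaptive rule is opt-in.

### GAM

GAM applies channel attention then spatial attention, each as a sigmoid gate
multiplied onto its input:

* **Channel**: the map is permuted so channels are the trailing axis and a
  two-layer perceptron (C → C/r → C, rectifier between, biases on both
  layers, weights shared across spatial positions) produces the gate.
* **Spatial**: a 7 × 7 convolution to C/r channels, batch norm, rectifier,
  a second 7 × 7 convolution back to C, batch norm, sigmoid. There is no
  pooling anywhere in this path.

With reduction r = 4 the parameter count has the closed form
25C² + 5C (`gam_param_count()`), which the tests verify against enumeration
of a constructed module for C ∈ {8, 64, 128, 256, 512}. The bias and
normalization placement above is the unique simple convention for which the
three head GAMs plus the three prediction convolutions total 8,622,262
parameters; alternatives (no MLP biases, batch norm after the MLP, bias-free
7 × 7 convolutions) all miss that total, which is why they were rejected.

## Loss

Localization uses the complete-IoU loss

$$L_{CIoU} = 1 - IoU + \frac{\rho^2(b, b^{gt})}{c^2} + \alpha v,\qquad
v = \frac{4}{\pi^2}\left(\arctan\frac{w^{gt}}{h^{gt}} -
\arctan\frac{w}{h}\right)^2,\qquad
\alpha = \frac{v}{(1 - IoU) + v},$$

where ρ² is the squared center distance and c² the squared diagonal of the
smallest axis-aligned box enclosing both boxes (the standard convention;
the quantity is otherwise underdetermined). α is a balance weight excluded
from gradients; the implementation freezes it at its current value and
differentiates the remaining expression. The gradient of the CIoU term with
respect to the four raw box activations is computed by central finite
differences (step 10⁻⁴) on the decoded box — cheap at the scale of matched
anchors, immune to algebra slips, and consistent with the frozen-α rule by
construction. All binary cross-entropy gradients are analytic.

The composite training loss is `0.05 * box + 1.0 * obj + 0.5 * cls`:
CIoU averaged over matched anchor–target pairs; objectness BCE on every
cell against the matched pair's CIoU value (clamped to [0, 1], zero
elsewhere) with per-scale balance weights 4.0/1.0/0.4; class BCE at matched
cells. Targets match an anchor when
`max(w/aw, aw/w, h/ah, ah/h) < 4`, assigned to the containing grid cell.
These weights and the matching rule follow common one-stage practice; only
the localization term's form is fundamental here.

## Metrics

* `iou()`, `ciou_loss()` — box geometry, vectorized over pairs.
* `accuracy()`, `recall()` — confusion-count ratios
  `(TP+TN)/(TP+FN+FP+TN)` and `TP/(TP+FN)`. True negatives are not
  meaningful for detection output, so `accuracy()` applies to abstract
  counts only.
* `average_precision()` — greedy score-ranked matching at a fixed IoU
  threshold (each ground truth used at most once), then the area under the
  precision–recall envelope by 101-point interpolation;
  `mean_average_precision()` averages IoU 0.50–0.95 in steps of 0.05. A
  printed "∫ P·R dR" style definition does not yield a usable metric, so
  the standard interpolated AP is used and cross-checked in the tests
  against a brute-force oracle.
* `rmse()`, `mae()` — per-image counting errors
  \(\sqrt{\tfrac1N\sum (p_i-q_i)^2}\) and \(\tfrac1N\sum |p_i-q_i|\).
* `mean_error_accuracy()` — relative counting error
  `100 * mean(|p_i - q_i| / q_i)` and its complement floored at zero. The
  field reports "mean accuracy" percentages without printing a formula;
  the relative-error convention is this package's documented choice.

## Data pipeline

* **Letterbox** (`letterbox()`): aspect-preserving rescale with the *fewest*
  padded pixels that reach stride-divisible dimensions — each output
  dimension is the smallest multiple of 32 covering the scaled image, the
  padding split evenly, gray fill (114/255). The geometry is exactly
  invertible (`letterbox_invert()`).
* **Mosaic** (`mosaic()`): four sources rescaled by U(0.5, 1.5), stitched
  around a center drawn uniformly from the middle half of a double-size
  working canvas, cropped back to canvas size; boxes remapped, clipped, and
  dropped below 25% surviving area. Deterministic per seed.
* **Anchors** (`best_possible_recall()`, `fit_anchors()`): before training,
  the label set is screened with the best-possible-recall rule (a box is
  coverable if some anchor passes the size-ratio test at threshold 4).
  When BPR ≥ 0.98 the default anchors are kept — the trainer logs this —
  otherwise anchors are refit by seeded k-means on whitened (w, h) with the
  guarantee that the returned set never has lower BPR than the default.
  No evolutionary refinement follows the k-means step, keeping the result
  deterministic.
* **Tiling** (`tile_image()`): sliding 640-px windows at stride 320 with
  the last window snapped to the border, for cutting large field images
  into network-sized pieces. The overlap and the 30% visibility floor are
  package choices.
* **Annotations**: Pascal VOC XML (1-based inclusive corners) and YOLO txt
  (normalized centers) readers/writers; all internal coordinates are
  0-based, half-open pixels.

## Synthetic scenes

`generate_scene()` renders spikes as textured rotated ellipses with a few
awn strokes over a low-frequency noise background, and returns exact tight
boxes over every rendered pixel. The generator emulates the three
difficulty factors of field imagery — density, box-level overlap (an
adaptive placement loop tracks a requested overlap fraction to within about
±0.1 for 30+ spikes, when the density makes the target geometrically
feasible), and spike–background color similarity (`green_similar` vs
`yellow_contrast`). It does *not* emulate perspective, lighting variation,
motion blur, growth-stage morphology, or photorealistic texture: green
tests on these scenes demonstrate that the pipeline's mechanics are
correct, not that the detector reaches field-grade accuracy, which requires
real imagery at real training scale.

## Training

`train_spike_yolo()` uses stochastic gradient descent with the published
optimizer settings for this detector family: initial learning rate 0.01,
momentum 0.937, weight decay 0.0005 (applied to convolution and perceptron
weights, not to biases or normalization parameters), batch size 8, default
60 epochs at 640 px. The schedule beyond the initial rate is a package
choice: 3 warm-up epochs ramping linearly, then cosine decay to 1% of the
initial rate. Mosaic augmentation is on (probability 1) during normal
training and off for overfitting checks. Batch normalization uses batch
statistics during training (eps 10⁻³, momentum 0.03 running stats) and
running statistics at inference, so repeated inference is bit-identical.

The test suite exercises the pipeline at desk scale — chosen so the suite
stays sharp rather than long: eight 320 × 320 synthetic scenes of 10 spikes,
30 epochs, batch 8. Under those conditions the total loss falls by more
than half, the anchor gate is exercised on both sides of 0.98, and a
ground-truth-echo detector scores RMSE = MAE = 0, mean accuracy 100%, and
mAP@0.5 = 1 through the full counting path.

## Numerical and design notes

* Weight init is Kaiming-style normal for convolutions and the GAM
  perceptron; prediction-conv objectness biases start at
  `log(8 / (640/stride)^2)` so early objectness probabilities are
  calibrated to a plausible object density.
* ECA lives on the output of the C3 fusion convolution inside ECA-C3. The
  3-parameter cost is position-independent, so parameter accounting cannot
  distinguish placements; this one keeps the gate after all channel mixing.
* NMS is greedy per class; a candidate is suppressed at IoU ≥ the
  threshold, so survivors have pairwise IoU strictly below it. Ties in
  score resolve by order of appearance.
* Degenerate inputs fail loudly: zero-area boxes, empty count series,
  all-zero confusion tables, zero ground truths for AP, and count series
  with `q_i = 0` for relative error all raise errors rather than returning
  NaN.
* Checkpoints are versioned single files holding config, parameters and
  batch-norm running statistics; `load_checkpoint()` rebuilds the model and
  reproduces identical predictions.

## Limitations

Pure-R training is CPU-bound and practical only at desk scale; training on
a real dataset (thousands of 640-px images, 60 epochs) needs a GPU
framework even though every operation here is mathematically equivalent.
The generator's stylized scenes cannot stand in for field imagery where
absolute accuracy claims are concerned. Oriented (rotated) boxes are out of
scope — boxes are axis-aligned throughout — and only single-class datasets
have been exercised, although `nc > 1` is plumbed through the head, loss
and decoder.
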