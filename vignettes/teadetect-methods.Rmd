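---
title: "Dense small-object detection for multimodal plant imagery: models and methods"
author: "teadetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense small-object detection for multimodal plant imagery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teadetect)
```

## The problem

Tea shoots — the young bud-and-leaf tips that premium tea is picked from —
are a hard detection target: a single overhead frame holds 200–400 of them,
each around 30×30 px or smaller on a 512×360 sensor crop, with chromaticity
close to the surrounding canopy. RGB alone is often not enough; a
time-of-flight camera supplies an aligned 16-bit infrared intensity image
and an 8-bit depth image that see the shoots even when color does not.
`teadetect` implements the full modelling stack for this setting: an
improved one-stage detector family, multimodal fusion at the data layer and
at the feature layer (the FFA module), object-based scale matching for
transfer learning between acquisition dates, and a synthetic scene
generator so that every component can be exercised without the original
field data.

## The detector family and its accounting

All variants are expressed as a `ModelConfig` (stem type, nominal
cross-stage-partial stage repeats, depth/width multiples, neck, neck-CSP
realization, input channels, classes, anchors) and expanded into a single
*blueprint* — an ordered DAG of typed blocks — that serves three consumers:
exact parameter counting, floating-point-operation accounting, and the
runtime network builder. One source of architectural truth means the number
you count is the number you run.

The baseline is the familiar "s"-scale one-stage design: a stride-2 stem
(space-to-depth slicing or its parameter-identical k=6 convolution
replacement), four CSP stages with nominal repeats 3,6,9,3, spatial pyramid
pooling, a top-down + bottom-up path-aggregation neck, three anchor-based
heads at strides 8/16/32. The improved variant reallocates stage repeats to
8,8,3,3 (more capacity at high resolution, where tiny objects still exist),
replaces the slicing stem by the k=6 convolution, the neck CSP's inner 3×3
convolutions by blockwise-quantized DSConv kernels (float-emulated, block
length 32, bit width configurable), and the path-aggregation neck by a
top-down feature pyramid.

Nominal repeats are scaled by the depth multiple with round-half-up and a
floor of one (`effectiveDepth`). At depth multiple 0.33 this collapses
distinct nominal allocations onto equal effective vectors — 8,8,3,3 ≡
9,8,2,2 ≡ 9,9,3,1 ≡ 8,9,2,2 — which is why those variants print identical
parameter counts.

**Counting conventions.** Two published conventions coexist for "number of
parameters". The training-time view counts convolution weights, biases and
both normalization affine terms per channel. The deployed view folds
normalization into the preceding convolution, leaving weights plus one bias
per output channel. The variant totals this model family publishes are the
*fused* counts — reconstructing the baseline under both conventions differs
by exactly one term per normalized channel (9,504 over the whole
single-class baseline) and only the fused counts match the published
variant totals, all eight of them, to the digit. `blockParameters` and `modelSummary`
expose both conventions; `modelSummary` defaults to fused.

**FPN realization.** "Replace the path-aggregation neck by a top-down
pyramid" admits more than one edit. The minimal edit (delete the bottom-up
branch) leaves a model about 1.19 M parameters lighter than the published
FPN variant; the classic FPN head — a full CSP stage on the stride-32
feature after pooling, then two top-down fuse steps, with heads reading the
three top-down outputs — reproduces the published 5,979,478 exactly. The
package builds the latter.

**FLOPs.** Per-layer cost is `2·C_in·k²·C_out·H_out·W_out` (two operations
per multiply-accumulate; the `literal` convention subtracting the one saved
addition is also available). Pooling, resampling and pointwise nonlinear
work are not counted; at the quoted one-decimal precision they are
negligible. The baseline at 640×640 totals 15.75 GFLOPs, printing as 15.8.

## The runtime network

The package carries its own CPU runtime: convolution as compiled
patch-extraction (im2col) plus BLAS matrix multiplication, batch
normalization with batch statistics in training and running statistics in
inference, SiLU activations, serial/parallel spatial pyramid pooling,
nearest upsampling, and a full hand-derived backward pass for every layer.
Every gradient path — convolution weights and biases, normalization scale
and shift, input gradients, and the composite CIoU box-loss gradient — is
verified against central finite differences in the test suite. Numerics are
double precision throughout.

## Loss, assignment and metrics

The objective is the standard three-term sum: binary cross-entropy
confidence (objectness) over every anchor/cell with IoU-valued soft targets
at assignments, binary cross-entropy classification (identically zero for
the single-class case), and a complete-IoU box term at assigned positions.
The breakdown is exactly additive by construction. Term weights follow the
v6.1 codebase realization (box 0.05, confidence 1.0 with per-level balance
4/1/0.4, classification 0.5) and are exposed as arguments; the CIoU
aspect-ratio coefficient is treated as a constant under differentiation, as
in the reference realization.

Targets are assigned by the wh-ratio gate (`max(r, 1/r) < 4` against each
anchor) to the center cell plus the two nearest neighbour cells, with the
sigmoid decode `xy = 2σ(t)−0.5 + cell`, `wh = (2σ(t))²·anchor`.

Evaluation decodes and suppresses (NMS IoU 0.45; confidence 0.001 for
average precision, 0.25 for reporting counts), matches greedily in
descending confidence with best-IoU tie-breaking, and integrates the
monotone precision envelope over recall (all-point interpolation). `map95`
is reported under the averaged IoU 0.50:0.95 convention — for ~30 px
objects the literal IoU = 0.95 quantity is near zero by construction, which
is incompatible with published magnitudes around 0.43; the literal value is
still available as `map95Literal`.

## Multimodal fusion

Three input-level compositions are provided: weighted pixel summation
(default weights 0.6/0.2/0.2 for RGB/IR/depth), RGBA stacking with the
alpha plane `0.5·IR + 0.5·depth`, and the D_IR_IR composite (depth,
infrared, infrared) feeding the second stream of the dual-stream model. All
are pixelwise in normalized [0, 1] space (re-quantization happens only on
write), hence commute with cropping.

The feature-layer path runs two unshared improved backbones and exchanges
information after each pyramid-producing stage through the FFA module:

1. per-channel 2-D FFT of both streams' feature maps;
2. *channel attention*: global max- and average-pooling of the magnitude
   spectra, the four vectors concatenated through a shared two-layer
   perceptron (input 4C, hidden C/2, output 2C) and a sigmoid, split into
   two per-stream channel weight vectors;
3. *frequency attention*: the two refined magnitude spectra stacked and
   passed through 1×1 conv → ReLU → 1×1 conv → sigmoid (input 2C, hidden
   C/2, output 2), giving two per-frequency weight maps;
4. inverse FFT (real part; the residual imaginary part of a round trip is
   at floating-point noise);
5. *cross re-enhancement*: each stream receives the other stream's purified
   map through two 1×1 convolutions, added residually.

Attention operates on magnitudes and multiplies the complex spectra by real
weights, so phase — the carrier of spatial structure — is invariant through
both refinement stages; the suite asserts this exactly. The re-enhancement
convolutions are plain linear maps with bias (near-identity
initialization), a deliberate choice: it makes the module's identity limit
exact (unit attention weights + identity convolutions reduce the whole
module to symmetric cross-addition, which the suite checks to 1e-12) and
keeps the cross-injected residual on the scale of the receiving stream.
The summation ablation (`useFFA = FALSE`) taps the plain sum of the two
streams for the fused pyramid while each stream continues with its own
features, which preserves the tied-weights symmetry (fused features equal
twice the single-stream features when both streams see the same image).

The perceptron sizings above are design choices — the published multimodal
parameter total depends on them and is therefore not an acceptance surface;
toggling FFA off strictly decreases the parameter count, which is.

## Object-based scale matching

Two acquisition dates ten days apart can shift the object-scale
distribution enough to hurt transfer. The package aligns a source dataset
to a reference by a single dataset-level factor `a = s_ref / s_src`, where
`s` is the mean *relative scale* — the geometric-mean side fraction
`sqrt(w·h / (W·H))`, chosen because the matching rule needs one symmetric
scalar per box. Every object above the judge threshold (default: the
reference mean) is cut out along its box, bilinearly resampled by `a`, and
re-pasted centered at its original position; for shrinking objects the
vacated ring is filled with the nearest context pixel of the pre-edit image
outside the original box, so no pixel is ever left unassigned (checked
exhaustively). Overlapping boxes are processed in decreasing-area order so
the smallest, hardest objects are pasted last; objects pushed past the
image border when enlarging are clipped. Matching is conservative: object
counts and class labels are invariant, and a second pass with the same
target has a factor of ~1.

The transfer workflow trains on the scale-matched source, then initializes
target training from the best source weights; the package records the
validation box-loss traces of a pretrained and a from-scratch run for
comparison.

## The synthetic scene generator

The generator emulates the statistical structure of the study corpus so
that every component is testable offline; it does not attempt
photorealism. Defaults are the study conditions: 512×360 frames, 200–400
objects, low chromatic contrast, depth 0.5–1.0 m stored 8-bit, void-prone
depth and speckled 16-bit infrared. Objects are rendered as anti-aliased
two-lobed quadratic strokes (bud + leaf) with random pose and elongation;
the three modalities share one object mask and are therefore pixel-aligned
by construction, with labels tight to the rendered strokes.

The reported corpus statistics are internally inconsistent: an absolute
object scale of about 30×30 px on a 512×360 frame is relative scale 0.07,
yet over 90% of objects are reported below 5% relative scale. Scale matching operates on the relative-scale
distribution, so the generator follows the latter: box scales are
log-normal (sd 0.30) around a configurable mean defaulting to 0.035, which
realizes ~92% of boxes below 0.05 and recovers configured means within a
few percent. Setting `colorContrast = 0` produces the hard multimodal case:
objects chromatically invisible in RGB yet present in depth, infrared and
the labels. Depth voids are zero-valued so they are distinguishable from
valid range; infrared speckle is multiplicative gamma noise with unit mean.

Generation is bit-reproducible: each scene runs in a private RNG stream
derived from its seed and restores the caller's generator state.

What passing tests on this generator do show: the correctness of the
geometry, accounting, fusion algebra, matching procedure and optimization
machinery, and the qualitative transfer-learning effect. What they do not
show: detection accuracy on real canopy imagery — real leaves have
structured clutter, specular lighting, motion blur and occlusion patterns
the generator does not model, and the published accuracy figures require
the original data at full training scale.

## Problem sizes and numerical choices

The suite and the worked examples run everything at reduced size, chosen as
the smallest scales at which each scientific claim is still meaningful:
shape and algebra checks at 64×64 inputs; the overfitting check trains the
improved preset on 8 synthetic images at 96×96 for 100 iterations, batch 4
(loss reduction ≥ 50%); the transfer comparison trains the source model for
150 iterations on 6 scale-matched source images, keeps its best (lowest
loss) weights as the pre-training checkpoint, and compares initial
validation box loss against random initialization on 12 target images over
5 seeds. The transfer comparison measures box loss specifically, and at
this input scale the default 640-resolution anchors dwarf the 4–8 px
synthetic objects, leaving the box term uninformative at initialization —
so that experiment uses `smallObjectAnchors()`, priors matched to the
tiny-object regime (the configuration explicitly supports small-object
priors; anchors do not enter the parameter/FLOP acceptance surface). The
overfitting check runs the preset's default configuration, where the
confidence term dominates and the reduction criterion applies to the
total.

Other numerical choices: He-scaled weight initialization with
prior-aware detection-head biases; SGD with momentum warm-up 0.8 → 0.937
and cosine learning-rate decay 1e-2 → 1e-5 over the iteration budget;
weight decay 5e-3 on convolution weights only (the reference schedule's
stated value, though tenfold the codebase default — flagged, configurable);
batch normalization epsilon 1e-5, running-statistics momentum 0.1; the
Focus stem rejects odd spatial sizes rather than padding (deterministic
shape contract); training images are letterboxed with grey fill 114/255.

## Known limitations

- Training is single-stream only; the dual-stream multimodal model
  supports forward inference and parameter accounting (its published total
  depends on unstated perceptron sizings and is not reproduced).
- DSConv runs as float emulation of the blockwise-quantized operator;
  integer-arithmetic inference kernels are out of scope, and the published
  DSConv-only parameter count (which encodes unstated quantization
  bookkeeping) is not an acceptance surface.
- The CPU runtime is a reference implementation: exact, verified, and
  deliberately simple; it is not performance-competitive with GPU
  frameworks and is sized for desk-scale experiments.
- The 75%-occlusion annotation rule of the original labeling protocol is a
  human criterion; it is documented but not computable from labels alone.
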