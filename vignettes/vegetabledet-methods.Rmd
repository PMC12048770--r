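---
title: "VegetableDet: model, training strategy, and desk-scale validation"
author: "vegdet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VegetableDet: model, training strategy, and desk-scale validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Greenhouse (protected) vegetable cultivation concentrates disease pressure:
warm, humid air favours pathogens, and dense planting means lesions appear
at every scale from millimetre specks on a single leaf to infections
covering whole plants, under lighting that ranges from dusk gloom to hard
specular reflection off waxy leaves, with plants occluding one another.
`vegdet` re-implements VegetableDet, a lightweight object-detection
framework designed for exactly this regime: it locates and classifies
disease lesions (30 disease classes plus healthy states across tomato,
cucumber, pepper, eggplant and squash) in RGB images, annotated in
PASCAL-VOC boxes.

Everything here runs on a CPU in plain R: the package carries its own
reverse-mode automatic differentiation on dense arrays, so the network,
its training strategy, and the evaluation suite are all testable without a
GPU framework. That choice caps the practical problem size (see
*Desk-scale sizes* below) but makes every computation in the pipeline
inspectable and exactly reproducible.

## Architecture

### Backbone with deformable attention

The backbone is a YOLO-family lightweight stack: a strided convolutional
stem, then CSP-style bottleneck blocks at strides 4 through 32. At the
stride-16 and stride-32 stages it inserts DAT (Deformable Attention
Transformer) blocks in pairs: a window-attention block followed by a
deformable-attention block.

* **Window attention** computes multi-head self-attention inside
  non-overlapping `window x window` tiles (default window 4). A shifted
  variant rolls the map by half a window and masks attention across the
  wrap-around seam, letting information cross tile borders in alternating
  blocks. When the configured window does not tile the map, the largest
  divisor of the extents is used instead of padding, so small maps degrade
  gracefully.
* **Deformable attention** lets the sampling locations of keys and values
  follow the content. Queries are a linear projection of the map; a light
  offset subnetwork (depthwise 3x3 conv, SiLU, pointwise 1x1 conv) maps
  grid-sampled queries to 2-D offsets, squashed by `tanh` and scaled so
  they are bounded by `offset_range_factor` (default 2) reference-grid
  cells; keys/values are projected from features bilinearly sampled at the
  displaced reference points. Attention uses a continuous relative-position
  bias, bilinearly interpolated from a learnable table because deformed
  positions are not integers. With the offset subnetwork at zero this
  reduces exactly to dense attention over grid-sampled keys/values, which
  is how the module is validated.

The reference grid defaults to half the feature extent per side, floored
at 2 points: a 1-point grid makes the attention softmax degenerate (a
single key receives all mass and the query/key projections stop receiving
gradient), so the floor keeps every parameter trainable even on tiny maps.
The standalone 4-stage extractor (`datForward`) embeds the image by a
4x4/stride-4 convolution and halves the extent per stage; stages 1-2
alternate plain and shifted windows, stages 3-4 alternate window and
deformable blocks. Blocks are standard pre-norm transformer blocks with
MLP expansion 4. Gradients for the bias-interpolation *positions* are
deliberately not propagated (the table values receive gradient; the
sampling location is treated as given) - a second-order refinement with no
practical effect at these scales.

### CSAAM neck

The neck is a top-down plus bottom-up feature pyramid over strides
8/16/32, fusing with 1x1 convolutions and placing one CSAAM
(channel-spatial adaptive attention) module after every fusion. CSAAM
chains:

1. channel gating `Xc = Yc(X) * X`, where `Yc` is a sigmoid over the sum
   of a shared bottleneck MLP applied to global max-pooled and global
   average-pooled channel descriptors (reduction 16, hidden width
   `ceiling(C/16)` and at least 1);
2. spatial gating `Xcs = Ys(Xc) * Xc`, where `Ys` is a sigmoid over three
   stacked 3x3 convolutions applied to the 2-channel (channel-max,
   channel-mean) descriptor - the triple replaces a single 7x7 kernel at
   the same receptive field with extra nonlinearity;
3. an identity residual `Y = Xcs + X`.

The residual is the plain identity shortcut: no extra transform is
specified anywhere for it, and the fixed point under zero-initialized
gates (`Y = 1.25 X`, both sigmoids at 1/2) makes the module's wiring
machine-checkable. Where the channel branch's textual description could
also be read as "multiply the two MLP outputs into the features and then
apply the sigmoid", we implement the standard pooled-MLP form
`sigmoid(MLP(max) + MLP(avg))`, which is the reading consistent with the
module diagrams and with the fixed-point contract.

### Head and loss

The head is anchor-free and centre-based, with an explicit objectness
branch: per level (strides 8/16/32) a shared 3x3 conv stem feeds 1x1
branches for class logits, objectness, and four log-distances to the box
sides in stride units (`side = exp(t) * stride`). The objectness branch
exists because the training recipe specifies an objectness loss gain and a
BCE positive weight for it; the result is a deliberate hybrid of an
anchor-free YOLOv8-style head with a YOLOv5-style objectness pathway.

Assignment follows the published training IoU threshold 0.2: a location is
positive for a box when its prior (a square of 4 strides per side centred
on the cell) overlaps the box with IoU at least 0.2 *and* the cell centre
lies inside the box (which keeps the log-distance encoding well defined);
contested cells go to the nearest box centre, and any box left without a
positive is force-assigned its best-IoU location. The loss is

```
total = 0.05 * box + 0.5 * cls + 1.0 * obj
```

with `box = mean(1 - IoU)` over positives, and `cls`/`obj` binary
cross-entropies with positive-sample weights 1. The objectness target at a
positive is the detached IoU of the currently decoded box (floored at
0.05), the YOLO-family "quality-aware" objectness: confidence learns to
rank localization quality, which materially improves mAP at matching
thresholds. With no positives in a batch the box and class terms are
exactly zero.

Decoding thresholds detections at `sigmoid(obj) * sigmoid(cls)` (default
floor 0.25), then applies per-class greedy NMS at IoU 0.45. By default the
surviving box is replaced by the confidence-weighted average of the
cluster it suppressed ("box voting"): with a dense grid of centre-based
predictions, neighbouring cells produce jittered versions of the same box,
and averaging them reduces that jitter; the survivor *set* is identical to
plain NMS (`merge_boxes = FALSE` disables it and is the form checked
against the brute-force NMS oracle).

## Training strategy

The two-stage hierarchical transfer protocol is implemented exactly:

* **Stage "init" (domain initialization)** - backbone and neck are copied
  from a source model; the head is freshly initialized; rates are
  backbone 3e-4, neck 1e-3, head 1e-3. The intended data scope is a
  single-vegetable (tomato-analog) subset, via `dataset_scope`.
* **Stage "diversity" (diversity adaptation)** - all weights carry over;
  three-tier rates backbone 1e-4, neck 5e-4, head 1e-3; the full
  multi-vegetable set with balanced sampling (per-image weight
  proportional to the inverse class count) and inverse-frequency class
  loss weights (normalized to mean 1).

Parameter groups are an exhaustive, disjoint partition by the leading name
component (`backbone.` / `neck.` / `head.`); an array outside those
partitions is an error rather than a silently defaulted group. DAT blocks
have no pretrained counterpart in common general-vision checkpoints, so
they are always freshly initialized whenever a source model lacks them.

The schedule ramps linearly for 3 warm-up epochs from 0.1 x base rate
(momentum from 0.8 to 0.937), then multiplies the rate by 0.8 every 30
epochs. The recipe's tabulated alternative (a stepped coefficient of 0.2)
is available via `decay_factor`; the prose factor 0.8 is the default
because the two sources conflict and the prose states the schedule
explicitly. The optimizer is Adam (beta1 = the configured momentum) with
weight decay 5e-4 applied in decoupled (AdamW) form to weight matrices
only - never to biases or normalization gains. Decoupled decay matters
here: the box gain 0.05 makes raw box-branch gradients small, and coupled
L2 inside the Adam normalizer would dominate them and pin the branch near
zero.

Online augmentation during training offers Mosaic (four seeded sources
scaled/cropped into the quadrants of a jittered centre split, boxes mapped
through each region's affine transform) and a per-sample random transform
drawn from the offline pool. Both act purely on the input pipeline; the
model topology is untouched.

## Synthetic scenes: what they emulate, and what they do not

The generator renders soil-textured backgrounds, elliptical leaves with
colour jitter, and lesion clusters whose colour encodes the disease class
(hues spread over the colour circle, skipping the leaf-green band). It
reproduces, with exact ground truth:

* the early/mid/late lesion-to-leaf scale progression, made quantitative
  as box-area fractions of the leaf area: early up to 5%, mid 5-40%, late
  above 40% (the source material is qualitative; these constants live in
  `stageFractions()` and are sampled per lesion);
* partial occlusion by overdrawn foreground foliage, with the covered
  fraction of each lesion measured exactly and recorded per box, so the
  annotation filters (drop occlusion > 85%, drop border boxes retaining
  < 15% of their extent) are testable against known truth;
* the four lighting regimes: normal (identity), low light (x0.45), strong
  direct light (x1.6, clipped), and strong reflection (seeded specular
  Gaussian highlights).

Scenes are a bit-exact function of the seed. What the generator does *not*
emulate: pathogen-specific lesion morphology (classes differ by colour,
not shape), leaf venation/texture realism, camera noise, and
multi-disease co-occurrence on one leaf. Consequently, a model that
performs well here has demonstrated that the architecture, losses,
assignment, optimizer and evaluation stack are wired correctly and can
learn colour-and-shape detection end to end - not that it would reach any
particular accuracy on real greenhouse imagery.

## Desk-scale sizes and the training smoke test

All tests run on one CPU against generated data. The sizes were chosen as
the smallest that still exercise every code path meaningfully: oracle
checks use 8x8 attention maps; the training smoke uses the tiny-width
model (`width_multiple = 0.25`, about 0.24 M parameters) on 128-pixel
single-leaf late-stage scenes - 200 training images over 4 classes, 60
validation images - for 10 epochs at batch size 4 with uniform-ish hot
rates (backbone/neck 5e-3, head 1e-2, one warm-up epoch), from-scratch
initialization, and the best-validation-mAP checkpoint retained, as in the
full recipe. Late-stage scenes at 128 px are used because they are the
largest-target regime: smaller canvases put lesion boxes only a few grid
cells across, where box regression accuracy is limited by resolution
rather than by the correctness this probe is after (held-out mAP@0.5
improves monotonically from 64 to 128 px under the identical recipe).
Validation decodes at a confidence floor of 0.01 (so average precision
sees the full confidence range; the 0.25 operating point only defines
P/R/F1) with box voting at NMS IoU 0.2 and horizontal-flip test-time
augmentation - with a coarse grid and single-object scenes, neighbouring
cells emit near-duplicate boxes that plain NMS at 0.45 leaves as false
positives, so the denser merge plus two-view fusion is the appropriate
decode at this scale. Training for the smoke draws the initial rate from
the top of the configured scratch range, because the two-stage recipe's
tiered rates presuppose a pretrained source model that a clean-room test
cannot assume.

## Numerical choices

* Coordinates are 0-based, half-open `[xmin, xmax)` in memory; VOC XML on
  disk is 1-based inclusive (the LabelImg dialect), converted at the I/O
  boundary.
* Feature tensors are `(C, H, W, N)` column-major arrays so a `(C, M)`
  matrix view is copy-free; matrix products go through BLAS.
* Softmax is computed with per-query max subtraction; BCE-with-logits uses
  the `log1p(exp(-|x|))` form; batch norm uses eps 1e-5 and momentum 0.1
  with running statistics for inference.
* Bilinear sampling uses align-corners normalized coordinates; points
  outside the grid clamp to the border and contribute zero gradient to
  their positions.
* Box-fragment rule: any transform that clips a box drops it when the
  retained area falls under 15% of the pre-clipping area, reusing the
  edge-annotation threshold for internal consistency.
* Ties in max-pooling argmaxes break to the first index, keeping backward
  passes deterministic.
* The planner's balancing arithmetic is exact (`copies = ceil(target/n) -
  1`, then delete the surplus augmented images), tightening "roughly
  equal" counts to exactly equal.

## Known limitations

* Pure-R training is slow; the practical envelope is tiny models on small
  images. The architecture code is identical at full scale, but full-scale
  training budgets are out of reach without a compiled framework.
* The synthetic class signal is chiefly colour; distributional results on
  synthetic scenes say nothing quantitative about real-field accuracy.
* `mAP` here follows the all-point (VOC-2010) interpolation; 11-point
  values would differ slightly.
* The "IoU threshold 0" evaluation mode means any-overlap matching; a
  literal threshold of zero would match disjoint boxes and is rejected as
  meaningless.
* Checkpoints are RDS files; they are portable across platforms but not
  across incompatible architecture configs (the config is stored and
  revalidated on load).
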