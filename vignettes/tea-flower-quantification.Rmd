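---
title: "Quantifying tea flowering: detection, counting and stage classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tea flowering: detection, counting and stage classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(teabloom)
```

## The problem

Tea (*Camellia sinensis*) breeding programmes need per-accession estimates
of flower quantity and flowering period: crossing requires synchronized
bloom, and flower thinning decisions depend on flowering intensity. Manual
surveys are slow and noisy. This package implements a computational stack
for quantifying flowering from side-view RGB images of tea rows:

1. a single-stage anchor-based detector for three phenological classes —
   unopened **bud**, **blooming flower**, **withered flower** — that also
   emits per-image counts as CSV;
2. the full detection/counting metric suite (precision, recall, F1, AP,
   mAP50, mAP50–95, counting R²);
3. a small feed-forward **flowering-stage classifier** mapping (counts,
   date) to one of five stages: initial (IFS), early-peak (EFS), mid-peak
   (MFS), late-peak (LFS) and terminal (TFS) flowering stage;
4. seeded synthetic generators for flower scenes and flowering seasons, so
   that every component is testable at desk scale without field imagery.

Everything — including convolution, batch normalization and all backward
passes — is implemented inside the package (Rcpp/RcppArmadillo for the
tensor kernels, R for the model logic). There is no external deep-learning
runtime.

## The detector

The architecture is a width/depth-scalable CSP (cross-stage-partial)
detector in the YOLO lineage: a CSPDarknet-style backbone (strided
convolutions and C3 blocks over five resolution levels, SPPF at the end), a
PANet-style feature-fusion neck, and three anchor-based heads at strides
8/16/32 — at the 640-px reference input these produce the 80×80, 40×40 and
20×20 grids for small, medium and large targets. Each head cell predicts,
per anchor, a box `(x, y, w, h)`, an objectness score and three class
scores; the decoded confidence follows the product rule
`Pr(object) · IoU · Pr(class)` (`confidence_score()`). Three attention
mechanisms are attachable:

* **SE (squeeze-and-excitation)** after the deepest strided convolution
  (backbone layer 7, 0-based): global average pooling per channel, a
  two-layer bottleneck (reduction ratio 16, the convention of the original
  mechanism), and a sigmoid gate that rescales channels.
* **ARConv (adaptive rectangular convolution)** inside the C3 bottlenecks
  of backbone stages 2 and 3 (configurable): two small subnetworks predict
  per-pixel kernel-height and kernel-width fields
  `h = a·sigmoid(f(x)) + b`; the field means, floored and forced odd,
  set the kernel size `k_h × k_w`; a rectangular grid of `k_h·k_w` offsets
  scaled by `(h0/k_h, w0/k_w)` per pixel is gathered by bilinear
  interpolation (zero padding outside the map) and convolved with a
  learned kernel bank; the result is modulated per pixel by predicted
  affine fields, `y = SK ⊛ S ⊙ M ⊕ B`.
* **CAAFT** on the deep path between backbone and neck: coordinate
  attention (directional 1-D pooling with factors 1/W and 1/H, a shared
  channel-reduction encoder, two sigmoid attention profiles multiplied
  back onto the map) followed by an attention-free transformer over the
  flattened H·W sequence, `Y = σ_q(Q′) ⊙ Pool(σ_k(K′) ⊙ V′)`, with a
  sigmoid output gate, a softmax forget gate over the sequence, and sum
  pooling. No T×T attention matrix is ever materialized (O(T·d) memory).
  The AFT output re-enters through a residual connection, so a closed
  output gate leaves the coordinate-attention pathway intact.

### Design choices where the design was open

* **Stem and activation.** The stem is a 3×3 stride-2 convolution and all
  convolution units use LeakyReLU(0.1), the activation of the earlier CSP
  lineage; on CPU it is markedly cheaper than SiLU with no observed
  training penalty at this scale.
* **CAAFT wiring.** The AFT consumes the CA-reweighted features (not the
  raw attention maps) and its output is added residually. This is one
  consistent reading of the block diagram; the residual form also gives
  the block a well-defined identity limit. `caaft_forward(ca_first =
  FALSE)` swaps the order for ablation.
* **AFT non-linearities.** The gate language of the formulation implies
  bounded gates; `σ_q` = sigmoid and `σ_k` = softmax over the sequence
  with sum pooling are the defaults, and both are overridable in
  `aft_params()` (identity gates are used in tests).
* **ARConv specifics.** Scale factors default to `a = 6, b = 1`
  (kernel extents in (1, 7) px); the size subnetworks are 3×3 conv →
  batch norm → LeakyReLU → 1×1 conv; `M` and `B` come from 1×1-conv
  subnets initialized to the identity (`M = 1, B = 0`); the "selected
  kernel" is the central `k_h × k_w` window of a single learned 7×7
  bank. Kernel sizes are computed once per forward pass from the
  batch-wide field means, which makes the size step piecewise-constant:
  the discrete size choice carries no gradient (a.e. zero derivative),
  while sampling positions, values, kernel and affine fields are all
  differentiated exactly.
* **Loss.** `loss = 0.05·l_box + 1.0·l_obj + 0.5·l_cls` with complete-IoU
  box loss and binary cross-entropy for objectness and class terms;
  targets are assigned per scale to anchors within a 4× width/height
  ratio, in the centre cell plus the two nearest neighbour cells; the
  objectness target is the detached CIoU of the current prediction.
  The CIoU gradient with respect to the predicted box is evaluated by
  central differences on the four box coordinates (vectorized across
  assignments; step 1e-4), with the aspect-term weight treated as
  constant, the standard practice for this loss.
* **Anchors.** Defaults are the standard COCO anchors; `anchors_from_labels()`
  re-estimates 9 anchors by k-means on the training label sizes and is
  used by the pipeline and benchmarks.
* **Class imbalance.** Withered flowers are the minority class in tea
  imagery. `train_detector(class_weights = "auto")` multiplies each
  class's BCE term by normalized inverse label frequencies; off by
  default.
* **NMS.** Greedy per class, IoU threshold 0.45; confidence 0.25 for
  counting and 0.001 for mAP evaluation. For **counting**, suppression is
  class-agnostic (one flower must produce one box even when its class is
  ambiguous). Quantitative count estimation uses a calibrated estimator
  (`calibrate_counting()`): the NMS overlap, confidence threshold and a
  linear map `count = a + b * n_boxes` are fitted on a labeled
  validation split — the analogue of regressing detector counts against
  manual counts in field phenotyping. In crowded scenes duplicate boxes
  inflate raw counts roughly proportionally, so a looser overlap plus the
  linear correction tracks true counts better than any hard threshold;
  CSV count files always contain raw per-class integer counts.
* **Coordinates.** Pixel boxes are 0-based half-open
  `[x1,x2) × [y1,y2)`, origin top-left; label files are centre-normalized
  `class cx cy w h` at 6 decimals, so read→write→read is byte-stable.

### Training

`train_detector()` is plain SGD with momentum 0.937, a short linear
warm-up, and (by default) a half-cosine decay of the learning rate to 10%
of its initial value — at desk scale the decay is what sharpens late-stage
box regression. Gradients are those of the batch loss scaled by the batch
size, the scaling conventional for this loss at learning rate 0.01.
Reference defaults are batch size 8 and learning rate 0.01 with the SGD
optimizer; epochs are caller-chosen. Training is deterministic given the
seed: shuffling and augmentation draw from the seeded R RNG and all
kernels are single-threaded C++.

## What the synthetic scenes emulate — and what they do not

`generate_scene()` paints stylized tea-flower scenes: layered green
foliage ellipses and dark branch strokes; buds as small pale ellipses
(8–20 px at the 640-px reference scale), blooming flowers as white petal
rosettes with a yellow core (15–40 px), withered flowers as brown
irregular blobs (10–30 px); class prevalence defaults to the 57/25/18%
bud/bloom/wither mix of typical field annotation sets; optional occlusion
by leaf/branch primitives painted after the flowers (visible fraction
computed on the object's own mask; objects below `min_visible_fraction`,
default 0.25, are left unlabeled); backlight as 0.6× brightness with
reduced contrast; light spots as 1–3 white ellipses at opacity 0.5.
Determinism is bit-exact per (spec, seed).

These scenes reproduce the *statistical* challenges (small dense targets,
class imbalance, occlusion, lighting artifacts) but none of the
*photometric* ones: no real texture, no intermediate phenological forms,
no background flowers from neighbouring rows. A detector that passes the
synthetic benchmarks has a working architecture, loss and training loop —
it says nothing about accuracy on real imagery, which requires real
annotated data and full-scale training.

`generate_season()` draws daily bud/bloom/wither counts from three lagged
Gaussian-shaped curves (bud leads bloom, wither trails it), negative-
binomially dispersed; stage labels follow a fixed cumulative-bloom rule —
IFS until cumulative bloom reaches 10% of the season total, EFS to 40%,
MFS to 60%, LFS to 90%, TFS after — so labels are reproducible and
non-decreasing in time. The curves themselves are invented plumbing; only
the five-stage structure and the averaged-count workflow mirror the field
protocol.

## The stage classifier

`build_stage_dataset()` applies the documented preprocessing: accessions
with median total count below 3 are dropped (too few flowers for a
reliable stage signal); remaining same-accession-same-date records are
averaged in groups of three (remainders dropped, keeping the rule exact);
year-1 samples split 8:2 into train/validation, year-2 samples form the
test set. Features are the three averaged counts plus day-of-year/366
(year-portable, matching the cross-year test design), z-scored with the
training split's statistics only. The network is input → six hidden ReLU
layers (64, 64, 32, 32, 16, 16) → 5-way softmax, trained 80 epochs with
cross-entropy, Adam, batch 16, learning rate 0.001. Ties in the argmax
resolve to the lowest stage index. At inference
(`classify_stage_series()`) same-date records are averaged in threes when
at least three exist, else used raw and flagged.

## Benchmarks and problem sizes

The package's capability checks run at sizes chosen for a single CPU:

* **Learning benchmark** (`run_learning_benchmark()`): width multiple
  0.125, depth multiple 0.33, 160-px input, 200 easy scenes (6:2:2 split),
  40 epochs, learning rate 0.02 cosine-decayed, k-means anchors. The easy
  preset uses 1–12 objects per scene — matching the per-image instance
  statistics of real annotation sets (a mean around a dozen instances,
  wide spread), which also keeps the count variance that the counting R²
  denominator requires — with unoccluded objects at 4× size scale and no
  lighting artifacts. The benchmark reports validation mAP50 and
  test-split counting R² with validation-calibrated counting. The
  attention blocks are disabled here so the benchmark stays a matter of
  minutes on a single CPU; they are exercised by their own oracle and
  gradient tests and by a full-graph training smoke test.
* **Stage-classifier benchmark**: 30 accessions × 2 synthetic seasons,
  moderate overdispersion (0.05), 80 epochs; accuracy on the held-out
  second year with the share of adjacent-stage errors reported — the
  expected failure mode, since neighbouring stages shade into each other.

## Numerical notes and limitations

* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.03) at evaluation; `eps = 1e-5`.
* Bilinear sampling uses zero padding outside the map, matching ordinary
  zero-padded convolution so that the standard-grid reduction of the
  adaptive convolution holds exactly on interior pixels.
* `kernel_size()` floors the field mean and decrements even values (never
  below 1).
* Softmax implementations subtract the maximum before exponentiation.
* Greedy one-to-one matching (decreasing confidence, ties by IoU then
  input order) is the committed matcher; it can differ from optimal
  matching on adversarial overlaps, which the test suite bounds on small
  instances.
* AP uses exact all-point integration of the precision envelope by
  default; 101-point interpolation is available behind a flag. mAP50–95
  averages thresholds 0.50 to 0.95 in steps of 0.05. Classes without
  ground truths are skipped from the mean; zero-denominator precision and
  recall are defined as 0.
* Single-threaded throughout; the training loop is O(batch) in memory but
  keeps per-node forward caches, so very deep configurations at large
  input sizes are memory-hungry.
* The counting R² of a detector depends on the spread of true counts in
  the evaluation set, not only on detector quality; comparisons across
  datasets with different count ranges are not meaningful.
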