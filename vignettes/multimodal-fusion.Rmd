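---
title: "Multimodal RGB-D fusion for fruit detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal RGB-D fusion for fruit detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitfusion)
```

## The problem

Detecting ripe fruit in orchard imagery is hard where it matters most:
under strong illumination changes, partial occlusion by leaves and
branches, and cluttered backgrounds whose colors and textures resemble the
canopy. RGB-only detectors degrade in exactly these conditions. The
approach implemented here attacks the problem at the *input* rather than
the architecture: an RGB-D camera provides aligned color, depth and
point-cloud data, and the detector consumes an 8-channel raster
[R, G, B, F, D, X, Y, Z] that stacks appearance (RGB), an engineered key
fruit feature map (F), metric depth (D) and per-pixel 3-D coordinates
(X, Y, Z). The appearance channels carry the discriminative color cues; F
distils them into an illumination-robust saliency map; D and XYZ carry
geometry that is unaffected by lighting altogether.

## The processing pipeline

### Point-cloud preparation

Clouds are accumulated from many near-simultaneous frames of a static
scene, so they are dense but noisy. Cleaning proceeds in two steps:

1. **Voxel downsampling.** Space is cut into cubic voxels (default edge
   5 mm, `voxel_size`) anchored at the origin, and the first point (in
   input order) of each occupied voxel is kept. The voxel index is
   `floor(coordinate / voxel_size)` per axis, so boundary ties fall to the
   lower-index voxel. Exact coordinate duplicates across frames are
   collapsed already at accumulation time.
2. **Statistical outlier removal.** For every point the mean Euclidean
   distance to its `k = 30` nearest neighbours is computed (the query point
   itself excluded). With `d` the vector of these per-point means, points
   with `d_i > mean(d) + 2 * sd(d)` are discarded. The mean and standard
   deviation are taken globally over all points — the standard
   statistical-outlier-removal formulation — and the 2-sigma multiplier
   follows the usual normal-theory argument that almost all inlier
   neighbourhood sizes lie within a few standard deviations of the mean.
   The kNN search is exact: a uniform grid hash with expanding shell
   search whose stopping bound guarantees the same result as brute force
   (the test suite checks equality against an O(N²) oracle).

A final rigid + scale transform (`world_transform`) places the cloud in
metric world coordinates; it defaults to the identity.

### 3-D to 2-D alignment

Projection uses a plain pinhole model with intrinsics (fx, fy, cx, cy) and
an extrinsic matrix that defaults to the identity (camera frame = world
frame). The chain is: extrinsic transform, perspective division
(`u = x fx / z + cx`, `v = y fy / z + cy`), a mirror flip of the column
coordinate only (`u' = mw - 1 - u`), and an additive offset correction
(`uo = u' + xoffset`, `vo = v + yoffset`). Conventions worth stating
explicitly:

* pixels are 0-based, `u` is the column and `v` the row; the in-image test
  is the half-open box [0, mw) x [0, mh);
* the mirror flip is part of the camera chain, applied only to `u`; the
  row coordinate passes through untouched;
* rounding to integer pixels (round half away from zero) happens only at
  rasterization, never inside the projection arithmetic;
* points that project outside the raster are dropped, not clamped —
  clamping would write spurious values into the XYZ border pixels;
* the offsets are per-dataset calibration constants with default (0, 0),
  loadable from a YAML/JSON calibration block.

Alignment can be verified visually with `mark_points_in_boxes()`, which
paints every cloud point projecting into a labelled 2-D box black and
leaves coordinates untouched.

### Key fruit features

Two per-pixel features are extracted from the color image:

* **Chroma (R−G).** Red-minus-green, computed in a widened range and
  clipped at zero. Red fruit gives a strong positive response; green
  foliage and gray branches give none. Clipping before normalization is a
  deliberate choice: negative (green-dominant) responses carry no fruit
  signal for red fruit.
* **Edges.** The image is converted to grayscale with BT.601 weights
  (0.299, 0.587, 0.114) and convolved with the 4-neighbour Laplacian
  `[[0,1,0],[1,-4,1],[0,1,0]]`; the absolute response is kept. Replicate
  (clamp-to-edge) padding keeps constant images identically zero. The
  8-neighbour kernel is available via `edge_kernel = "lap8"`.

Both maps are min-max normalized per image to [0, 1] (a constant map
normalizes to zeros rather than dividing by zero) and fused as
`F = 0.6 * chroma + 0.4 * edge`. The 6:4 weighting favours the chroma
response, with edges contributing shape/contour evidence; because F is a
convex combination it stays in [0, 1]. Per-image normalization also makes
F invariant under a global illumination gain, which is precisely the
robustness the fused channel is meant to contribute.

### 8-channel composition

`compose()` stacks [R, G, B, F, D, X, Y, Z]: RGB rescaled to [0, 1], F as
computed, D decoded from Z16 (16-bit unsigned millimeters; 0 and anything
beyond the 4 m sensor range are no-data) and the XYZ bands rasterized from
the cleaned cloud through the full camera chain. Where several points land
on one pixel the nearest (smallest camera depth) wins — the
occlusion-correct rule. Unsampled pixels hold zeros in D and XYZ; this is
where the pipeline's "fill empty regions with zeros" happens, at the
raster level, since zero-filling an unordered point *set* is not
meaningful. Containers round-trip losslessly (float64 binary + JSON
sidecar with band names and provenance).

At training time a *view* of the container is taken: D and Z divided by
the 4 m range, X and Y by a fixed scene half-extent (default 2 m). Raw
meters always stay in the container; the view only conditions the network
input.

## Anchor optimization

Anchor priors are checked before training. For a box and an anchor the
mismatch is `r = max(w/wa, wa/w, h/ha, ha/h)`; a box *matches* an anchor
when `r < 4` (the `ratio_threshold`). Two summary rates are computed
against the nine default priors (10x13 ... 373x326): AAT, the mean per-box
fraction of matching anchors, and BPR, the fraction of boxes whose best
anchor matches — an upper bound on achievable recall. If BPR is at least
0.98 the defaults are kept. Otherwise the anchors are re-estimated:

* **k-means** on (w, h), normalized per axis by the maximum, Lloyd's
  algorithm for 30 iterations, seeded initialization from k distinct
  boxes. Empty clusters keep their previous centroid. The implementation
  is a small explicit Lloyd loop because the pipeline needs a
  per-iteration objective trace (its monotonicity is a tested invariant)
  and deterministic initialization; `stats::kmeans` serves as an
  independent cross-check in the tests.
* **Genetic refinement**: an elitist single-population search. Each
  generation mutates every anchor dimension with probability 0.9 by a
  multiplicative factor near 1 (spread 0.1, clipped to [0.3, 3]) and keeps
  the candidate only if its fitness improves. Fitness is the mean over
  boxes of `1 / r_best`, counted only when `r_best < 4`; boxes without a
  matching anchor contribute zero, which is what penalizes overly small
  anchor sets. Defaults: 1000 generations. The exact functional form of
  the fitness is a reconstruction; the thresholded mean of inverse ratios
  is the simplest form consistent with "ratio-based fitness plus a
  threshold that sieves out diminutive anchors".

The returned set is never worse (by BPR) than the defaults.

## The detector

The full reference detector family is deliberately **not** replicated.
The scientific claim under test concerns the *input layer*: a 6x6,
stride-2 convolution whose kernel bank is W x H x m x n = 6 x 6 x m x 32,
where only m — the channel count — changes between configurations (3 for
RGB up to 8 for the full stack). Its output passes through a
parameter-free per-channel spatial normalization (zero mean, unit
variance over the image, per filter) before the bias and activation: the
reference detector family normalizes after every convolution, and
normalizing here — the one layer whose fan-in varies with m — removes the
input-scale confound from the channel-count comparison without adding
parameters, so the first-layer parameter count stays exactly
6 * 6 * m * 32 + 32. Everything downstream is a compact stand-in chosen
to keep training tractable on a single CPU: three 3x3 convolutions (two
stride-2; widths 48, 64, 64, leaky-ReLU 0.1) and a 1x1 anchor-based head
on a single stride-8 grid predicting (objectness, tx, ty, tw, th) per
anchor. Parameter counts and layer shapes downstream are independent of m
by construction.

Training follows the stated schedule: SGD, batch 4, initial learning rate
0.01 decaying linearly to 1% of its initial value across the epoch
budget, momentum 0.937 (0.8 during warm-up), L2 weight decay 5e-4 on
convolution weights, and a 3-epoch warm-up during which the bias learning
rate starts at 0.1 and the weight learning rate ramps from 0. Targets use
the standard dense assignment of this detector family: every anchor
matching a box within the ratio threshold is positive at the box's center
cell and its two nearest neighbour cells; the bounded decode
(center `2*sigmoid - 0.5` cell units, size `anchor * (2*sigmoid)^2`)
reaches all of them. Objectness is trained with binary cross-entropy
towards the IoU of the currently decoded box (soft targets), with a
moderate (10x) positive up-weight against the overwhelming background
mass; box residuals carry weight 5. Inference keeps detections with
confidence at least 0.25 and applies greedy NMS at IoU 0.45; evaluation
declares a true positive at IoU 0.5 with greedy one-to-one matching in
descending confidence. The 0.5/0.25/0.45 thresholds are conventional
defaults, config-exposed.

Training augmentation applies horizontal flips (to all bands and boxes;
the X band's values change sign under a mirror, because X grows with the
image column) and photometric gain/noise to the RGB bands only. F is left
untouched
because per-image min-max normalization makes it invariant under a pure
gain; rotation, scale and crop augmentation were left out to keep the
desk-scale budget, a simplification that matters little for the
directional comparison since both arms see the same augmentation.

## Synthetic scenes

The generator stands in for an orchard RGB-D dataset that is not
distributable. One seed fixes a scene completely. A scene is rendered
through the very camera chain the pipeline assumes (including the mirror
flip), into a single z-buffer from which *all* outputs derive — color
image, Z16 depth raster, point cloud (every valid pixel back-projected,
with its color) and labels. Shared provenance makes the cross-modal
consistency properties exact: depth raster vs cloud Z agrees to the 1 mm
encoding quantum, and the fraction of zero-filled XYZ pixels falls as
cloud density rises.

Scene content and the reasoning behind the defaults:

* **Fruits**: `n_fruits = 6` ray-traced spheres of radius 3-5 cm (apple
  scale) at 0.4-1.8 m — close-range capture typical of harvesting
  platforms, inside the sensor's 0-4 m envelope. Shading is a simple
  headlight model with per-fruit tint jitter.
* **Clutter**: 25 ellipses per scene — green "leaves" and elongated brown
  "branches" — at random depths, plus a mottled green/brown far wall at
  3.2-3.9 m.
* **Illumination**: one global RGB gain per scene drawn from [0.4, 1.3],
  emulating capture sessions from dim to bright light. The gain is applied
  after geometry, so depth, cloud coordinates and labels are provably
  unaffected by it.
* **Occlusion**: with probability 0.3 a fruit receives a dedicated
  occluding leaf in front of it, in addition to incidental fruit-fruit
  and clutter occlusion. Visible fractions are measured by z-buffer pixel
  counting (exact at raster resolution), and fruits more than 80% occluded
  are omitted from the labels, matching the annotation rule. Label boxes
  are the image-clipped extent of the *unoccluded* silhouette, as a human
  annotator boxes a partially hidden fruit.

What the generator does **not** emulate: real sensor noise structure
(stereo shadowing, speckle, depth quantization beyond 1 mm), texture,
specularity, and the long-tail variety of real canopies. Passing tests on
these scenes therefore demonstrate the pipeline's internal consistency and
the direction of the channel-configuration effect, not field performance.

## The channel-configuration experiment

`run_experiment()` generates one dataset (70/10/20 split), preprocesses
every scene once to the full band library, and trains/evaluates each
requested channel configuration under identical budget and seeds; the
only difference between arms is the input-layer channel count m. The
package's desk-scale experiment uses 200 scenes at a quarter of the full
848x480 resolution (212x120, intrinsics scaled together), 12 epochs and 3
training seeds per arm, reporting the median F1 per arm — problem sizes
chosen so the full comparison completes in minutes on one CPU while
leaving the detector enough budget to reach stable mid-range F1. The
tested claim is directional: the 8-channel [RGB+XYZ+D+F] arm should not
trail the RGB-only arm, because F, D and XYZ are invariant to the
illumination gain that corrupts RGB across scenes.

Two caveats temper the desk-scale version of this comparison. First,
per-run F1 varies by several points across training seeds at this budget,
so a 3-seed median is a noisy estimator. Second, a wider input layer has
more first-layer parameters to fit in the same number of SGD steps, which
works *against* the 8-channel arm whenever the extra channels' marginal
information is small — and the synthetic scenes' RGB signal is cleaner
than real orchard imagery. The acceptance script reports the measured
medians for both arms, so the outcome of the comparison is inspectable
rather than asserted.

## Numerical choices and degenerate inputs

* Constant feature maps normalize to zeros (no division by zero).
* `remove_outliers` returns the cloud unchanged (with a warning) when
  N <= k; removal uses a strict inequality, so a zero-spread distance
  distribution removes nothing.
* Voxel boundary ties go to the lower-index voxel via `floor`.
* Rasterization rounds half away from zero; ties in NMS and matching are
  broken by descending confidence, first-come on equal confidence.
* The projection guards `z > 0` and reports behind-camera and
  out-of-image counts separately.
* Seeds: every stochastic step (scene generation, splits, k-means
  initialization, GA mutations, weight initialization, shuffling,
  augmentation) takes an explicit seed and restores the caller's RNG
  state.

## Known limitations

* The compact trunk saturates well below the reference detector's
  capacity; absolute P/R/F1 on the synthetic scenes are not comparable to
  published orchard-data results and are not meant to be.
* Single-class only; the class term of the usual detection loss is
  degenerate and omitted.
* The offset-correction constants default to zero; real rigs need
  calibration values in the config.
* PLY I/O covers XYZ + 8-bit RGB vertices (ascii and little-endian
  binary), not meshes or list properties.
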