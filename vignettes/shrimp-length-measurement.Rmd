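---
title: "Measuring curved shrimp bodies: models, algorithms and design choices"
author: "shrimpline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring curved shrimp bodies: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrimpline)
```

## The measurement problem

The body length of farmed shrimp is the standard proxy for growth rate and
biomass, but shrimp lie in curved, twisted postures, overlap each other, and
their translucent bodies blend into light container floors. A straight-line
measure (bounding-box diagonal, Feret diameter) is therefore meaningless;
the quantity of interest is the **arc length of the body centerline** — the
curve equidistant from the two flanks — converted to millimetres through a
camera calibration.

`shrimpline` implements a two-stage measurement pipeline:

1. **Instance stage** — one binary mask per animal. Any instance
   segmentation model can supply these through COCO-style JSON
   (`load_external_masks()`); for synthetic work the package ships a
   classical stand-in (`segment_instances()`): intensity thresholding
   against the background median (Otsu by default), distance-transform
   watershed to split touching bodies, and a minimum-area speckle filter.
2. **Centerline stage** — for each instance, the RGB image and the mask are
   concatenated to a four-channel tensor and reduced back to three channels
   by a learned 1×1 convolution (`fuse_inputs()`). A small
   encoder/ASPP/skip-fusion network predicts a per-pixel centerline
   probability map, which is binarized, thinned to one pixel width
   (Zhang–Suen), pruned to a single endpoint-to-endpoint path, measured in
   pixels and converted to millimetres.

Three comparative baselines operate on the mask alone: polynomial curve
fitting after image-moment alignment (PCFM), a Voronoi-type medial axis
with longest-path burr pruning (VDBM), and the plain morphological
skeleton. All four routes share one measurement code path (thinning,
pruning, chain-length estimation, calibration), so differences in accuracy
reflect the centerline source, not the measurement plumbing.

## The centerline network

The network is deliberately small and written from first principles
(forward and backward passes over Rcpp/Armadillo convolution kernels):

* a plain convolutional encoder of `encoder_depth` stages (two 3×3
  convolutions + ReLU, then 2×2 max pooling; stage *i* has
  `base_channels * 2^(i-1)` channels);
* an **ASPP block** at the deepest resolution: parallel 3×3 convolutions
  with dilation rates `aspp_rates` (default `{1, 2, 4}` at desk scale — the
  classical `{1, 6, 12, 18}` rates are designed for much larger inputs),
  concatenated and merged by a 1×1 convolution. A 2^depth-downsampled copy
  of the fused input is concatenated with the deepest encoder features
  before the ASPP (`inject_downsampled_input`), giving the context block
  direct access to raw colour cues;
* a decoder that upsamples (nearest-neighbour), concatenates the encoder
  skip connection of the matching resolution, and refines with a 3×3
  convolution per stage;
* a final 1×1 convolution and sigmoid. The head bias is initialized at −2
  so the initial probability map reflects the extreme rarity of centerline
  pixels.

Targets are **3-px-wide bands**: the ground-truth polyline is rasterized to
an 8-connected one-pixel curve and dilated once with a 3×3 square element.
One-pixel targets give near-zero gradient signal under any overlap loss;
the 3-px band is the narrowest target that trains stably.

Training uses the composite loss

$$L = L_{Dice} + \beta\, L_{BCE}, \qquad
L_{Dice} = 1 - \frac{2\sum_i Y_i \hat Y_i + \epsilon}
                    {\sum_i Y_i + \sum_i \hat Y_i + \epsilon},$$

with binary cross-entropy averaged over pixels and the same $\epsilon$
(default $10^{-6}$) in both terms. The Dice term carries most of the signal
for thin structures (foreground is well under 5 % of pixels); $\beta$
(default 1) balances the pixel-wise term. Optimization is momentum SGD
(momentum 0.9) with a multi-step learning-rate schedule; one integer seed
fixes initialization, data order and augmentation, making training runs
bit-reproducible. Augmentation is restricted to flips and right-angle
rotations.

### The desk-scale reference configuration

All shipped tests and the acceptance script use a configuration sized for a
single CPU: 20 single-instance 96×96 crops, `base_channels = 8`,
`aspp_rates = c(1, 2, 4)`, 30 epochs, initial learning rate 0.05 decayed
×0.1 after epochs 20 and 27, batch size 2. This trains in about a minute
and reaches a held-out pixel F1 above 0.8. A full-scale deployment would
use the package defaults (`train_config()`: 40 epochs, learning rate 0.02)
on thousands of instances; nothing in the architecture is specific to the
desk scale. Training inputs use *detected* masks (the stand-in segmenter)
with ground-truth centerline targets — the same strategy used to build
mask-to-centerline datasets in practice, and it matches the inference-time
input distribution.

## From band to millimetres

`measure_band()` is the single measurement path shared by every method:

1. **Zhang–Suen thinning** (`zhang_suen_thin()`): the classic 1984
   two-subiteration algorithm, iterated to its fixed point (idempotent by
   construction). We implement the published conditions literally; note
   that the literal algorithm deletes isolated 2×2 squares and erodes
   near-diagonal band tips — see "measurement corrections" below.
2. **Longest-path pruning** (`skeleton_to_path()`): the skeleton pixels
   form an 8-connected graph with Euclidean edge weights; the path returned
   is the longest geodesic between endpoints (degree-1 pixels), which
   removes burrs. Disconnected skeletons fall back to the largest component
   and are flagged.
3. **Chain length**: `arc_length_px()` defaults to the Euclidean step sum
   (1 orthogonal, √2 diagonal). That sum is the natural geometric
   definition but is a *biased* estimator of digitized curve length (up to
   +8.2 % at 22.5°); the measurement path therefore uses the calibrated
   chain-code weights 0.948/1.340, the classical unbiased estimator for
   digitized lines of random orientation.
4. **Tip reconstruction**: two-subiteration thinning retreats from band
   tips — about half the band width normally, but tens of pixels on
   near-diagonal stretches (a verified property of the literal algorithm).
   Each path end is extended by `max(h, T - h)`, where `h` is the band's
   distance-transform value at the endpoint and `T` the geodesic extent of
   the band beyond that endpoint (multi-source geodesic distance from the
   path). With no erosion `T ≈ 2h` and the correction reduces to the
   classical tip-radius term of vermiform morphometry; with erosion it
   restores the eaten stretch. On 4×200 synthetic bodies (width 5–11 px,
   length 100–275 px) this chain recovers true length with a mean bias of
   +1.1 % and 100 % of instances within 5 %.
5. **Calibration**: multiplication by `mm_per_px`, a scalar obtained from a
   reference object at fixed camera geometry. It is always supplied
   explicitly (for synthetic scenes it comes from the scene config).

The **baselines are measured as published** — thinning, pruning, calibrated
chain length — *without* tip reconstruction: head/tail shortfall is their
documented failure mode, and it is precisely what the comparative study
quantifies (the medial axis of a capsule ends one cap radius short of each
tip; the closed-form capsule check uses cap radius 7.5 px because raster
quantization limits end localization to about one pixel, so the ±10 % band
must be wide relative to that). The framework's band route additionally
uses **hysteresis binarization** (strong threshold 0.5, weak 0.1): weak
pixels are kept only when 8-connected to a strong pixel, extending the band
through low-confidence stretches — faint body parts, tips — without
admitting isolated noise.

## The synthetic scene generator

`generate_scene()` emulates the study system: a top-down view of a light
container holding 10–18 curved translucent bodies of 40–110 mm at roughly
0.5 mm/px.

* **Geometry**: a natural cubic spline through 4–6 control points with
  lateral offsets scaled by the dimensionless `curvature` parameter, scaled
  to an exact target arc length; the body is a disk swept along the spline
  with radius profile $r(t) = r_{max}(0.35 + 0.65 \sin \pi t)$, tapering
  toward head and tail. Centerlines are rejected as geometrically invalid
  when the bend radius falls below the body width or when stretches more
  than three widths apart along the body approach within `width + 4` px —
  a real body cannot fold into itself, and such masks would self-merge,
  making length unrecoverable for any method (including manual
  annotation).
* **Appearance**: bodies are alpha-composited over the background with
  translucency increasing from head (α ≈ 0.75–0.9) to tail (α ≈
  0.15–0.3) and a body tone close to the container floor — the tail of a
  live grey shrimp is markedly harder to see than the cephalothorax.
  Gaussian noise (default σ = 2/255) is added and the image quantized to 8
  bits.
* **Ground truth**: each instance stores its mask (a single 8-connected
  component), the sub-pixel centerline polyline, and its exact arc length
  in px and mm. With `allow_overlap = TRUE` masks stay amodal (full,
  unoccluded); a `"visible"` occlusion mode subtracts later-drawn bodies
  instead.

What the generator does *not* emulate: water caustics and refraction,
motion blur, specular glints, legs/antennae, and real annotation noise.
Passing tests on synthetic scenes therefore demonstrate the correctness and
internal consistency of the algorithms under known truth — not field
performance on real imagery.

## The comparative study

The benchmark mirrors the evaluation protocol of a full deployment: the
*complete* pipeline runs on stand-in detector masks (not ground truth),
because that is what all methods receive in practice. On 150 held-out
synthetic bodies the framework attains the lowest MAE, followed by the
morphological skeleton, with PCFM and VDBM clearly behind; PCFM
additionally fails outright on S-shaped postures (its fitted curve deviates
beyond the body half-width after moment alignment — the centerline is not a
function of the aligned abscissa), and VDBM carries its characteristic cap
shortfall. On *perfectly visible* synthetic bodies with exact masks the
classical routes are near-optimal and the learned route has no advantage;
the ordering above emerges exactly when segmentation is imperfect
(translucent tails), which is the operating regime the system targets.

Evaluation metrics (`mae_rmse()`, `centerline_scores()`, `mask_ap()`)
follow the standard definitions; mask AP uses COCO-style 101-point
interpolation with score-descending greedy matching, `mIoU` averages
foreground and background IoU (two-class convention), and degenerate 0/0
ratios are defined as 0. Measured instances are paired with ground truth by
mask IoU ≥ 0.5, greedily, one-to-one; unmatched instances are counted and
excluded from error aggregates.

## Numerical and degenerate-input choices

* Images are scaled to [0, 1] before fusion; 8-bit inputs are divided by
  255.
* Inputs whose spatial dims are not divisible by `2^encoder_depth` are
  reflect-padded and cropped back after the forward pass.
* The neighbourhood code orders the eight neighbours clockwise from north
  (P2…P9); borders are zero-padded.
* A skeleton with no degree-1 pixel (a ring) falls back to the graph
  diameter; a single-pixel skeleton has length 0.
* An empty prediction yields precision 0 (avoiding 0/0); an empty band
  yields an `NA` measurement, which the pipeline counts and excludes.
* Moment alignment ties (`mu20 == mu02`, `mu11 == 0`) default to 0°.
* Training aborts with the epoch index if the loss becomes non-finite.

## Known limitations

* The stand-in segmenter is a deliberately classical placeholder; its
  scores are normalized areas, not calibrated confidences (AP numbers on
  synthetic scenes exercise the ranking logic, nothing more).
* The literal Zhang–Suen algorithm does not preserve connectivity for
  arbitrary shapes (isolated 2×2 squares vanish); on centerline bands and
  body masks — its operating domain here — connectivity is preserved, and
  the tip reconstruction compensates its diagonal erosion.
* The desk-scale network is trained on 20 instances; it reproduces the
  qualitative behaviour of the full-scale system, not its headline
  accuracy.
* Lengths are reported for the largest skeleton component only; bodies
  whose predicted band disconnects across a wide invisible stretch are
  measured short.
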