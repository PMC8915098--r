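---
title: "Detecting and mosaicing the retinal window in smartphone ophthalmoscope video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and mosaicing the retinal window in smartphone ophthalmoscope video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retistitch)
```

## The problem

A smartphone ophthalmoscope (a D-Eye-style clip-on lens) records retinal
video of very different character from a desktop fundus camera: a small
bright circular window of visible retina floats on a near-black surround,
illumination drifts from frame to frame, and the field of view is so narrow
that no single frame shows much anatomy. Two processing tasks follow
naturally and this package implements both, classically, end to end:
locating the retinal window in every frame, and stitching the located
windows into one wider-field mosaic.

## Intensity normalization

All stages assume frames of comparable brightness. Given a set of frames,
each frame's mean intensity (over all pixels and channels) is computed, the
set minimum $I_{\min}$ is found, and every frame is rescaled by
$I_{\min} / I_{X\text{mean}}$, a ratio in $(0, 1]$. After this every float
mean equals $I_{\min}$ exactly; quantizing back to 8 bits (round half up)
perturbs means by less than half an intensity level. Because $I_{\min}$ is a
set statistic, the whole set must be seen before any frame is emitted —
streaming callers must buffer. The mean is taken jointly over the three
channels and the scale applied uniformly, which preserves hue; a per-channel
variant was considered and rejected as it would shift color balance between
frames.

## Detection: the classical chain

`detect_retina()` composes five steps, each exposed and tested separately:

1. **Red channel.** The retinal window is red-dominant and the surround is
   not; the R plane carries the contrast.
2. **Gaussian blur** (`blur_kernel`, default 9, σ from the usual
   `0.3·((k−1)/2 − 1) + 0.8` heuristic) smooths sensor noise so the
   threshold step produces clean region boundaries.
3. **Otsu threshold** on the 256-bin histogram, maximizing between-class
   variance; on a plateau of equally good thresholds the midpoint is taken.
   Constant images have no valid split and are reported as degenerate — the
   chain turns this into a clean no-detection result (the realistic outcome
   for an all-black or saturated frame).
4. **Contour image**: the 8-connected boundary of every foreground
   component, drawn black on white. Interior structure (vessels) vanishes
   here, which is exactly what the circle detector wants.
5. **Circle Hough Transform** over radii in
   `[min_radius_frac, max_radius_frac]·min(H, W)` (defaults 0.10 / 0.45).
   Every edge pixel votes for candidate centers at each radius; a
   candidate's score is its supported fraction of perimeter, which makes the
   acceptance threshold (`accumulator_threshold`, default 0.25)
   radius-invariant. Ties are broken deterministically (larger radius, then
   smaller y, then smaller x) and near-duplicate centers are suppressed
   within 10% of the image diagonal. The top circle's enclosing square,
   rounded half away from zero and clipped to the image, is the detection.

Two practical notes. The chain runs at an internal working resolution
(`working_width`, default 480 px on the longest side) and scales the circle
back: at the scale of the retinal window, full-HD resolution adds cost
(≈50×) but no localization accuracy beyond the box-rounding already implied
by evaluation. And the whole detector is a contract — anything mapping a
frame to a `detection_result` can replace it. For interoperability with the
common single-class learned detector, `derive_yolo_config()` reproduces the
standard configuration arithmetic (`max_batches = max(2000·classes, 6000)`,
steps at 80%/90% of that, `filters = (classes + 5)·3`), but no network is
shipped, trained, or required.

## Cropping

`crop_and_pad()` copies the detected box unchanged onto a black 400×400
canvas, centered. Scale is never altered — mosaicing assumes all crops share
one scale — so a crop larger than the canvas is center-cropped (with a
warning) rather than downscaled. The canvas default and the
preserve-scale-at-all-costs policy follow standard practice for this data;
black padding matches the surround and is neutral for the validity masks
used later. `resize_percent()` (bilinear, dimensions floored) serves the
high-resolution reference imagery instead: floor is the rounding that maps a
2912-pixel side at 15% to 436, the conventional value.

## Registration

Keypoints are multi-scale Harris corners: at σ ∈ {1.5, 3, 6} the
structure tensor of the smoothed image is integrated at 1.5σ (via an
iterated box filter — three boxes approximate the Gaussian and cost O(1)
per pixel), the scale-normalized corner response is thresholded relative to
its maximum (`response_frac`, default 1e-4), and 3×3 local maxima are
refined to sub-pixel by a quadratic fit. Each keypoint gets a dominant
gradient orientation (36-bin weighted histogram, parabolic peak
interpolation) and a 4×4×8 gradient histogram descriptor over a rotated
16×16 sample grid — the SIFT recipe — post-processed to root-SIFT:
L1-normalize then take element-wise square roots, leaving unit L2 norm so
Euclidean distance compares descriptors. This classical stage deliberately
stands in for a learned keypoint network; the `keypoint_set` shape is the
contract.

Matching is nearest-neighbour with Lowe's ratio test (default 0.8) and
injectivity on the following image. The homography (following → base) is
estimated by RANSAC over normalized-DLT 4-point hypotheses (tolerance 3 px,
99.9% adaptive termination), then refit by DLT on the consensus set and
polished by Gauss–Newton on the geometric transfer error. On synthetic pairs
in the small-motion regime this recovers all four corner reprojections
within 1 px in ≥ 95% of seeded trials — the regime matters: hand-held video
of a steady eye produces small inter-frame transforms, and the estimator is
tuned for that, not for wide-baseline panoramas.

## Blending and the sequence driver

For two warped images on a shared canvas with validity masks $m_1, m_2$ and
overlap $R = m_1 \wedge m_2$, let $d_i$ be the exact Euclidean distance to
the nearest pixel of image $i$ outside the overlap. Then

$$w_1 = \begin{cases}0 & m_1 = 0\\ d_2/(d_1+d_2) & m_1 = 1 \wedge R = 1\\ 1 & \text{otherwise,}\end{cases}$$

symmetrically for $w_2$, and the mosaic is $w_1 I_1 + w_2 I_2$ per channel.
Each image fades out toward its own boundary; the weights sum to 1 on the
overlap, so seams are monotone ramps rather than steps. The distance
transform is exact (Felzenszwalb–Huttenlocher), not a chamfer
approximation. One degenerate case needs a policy: an image entirely inside
the overlap has no "outside" pixel and its distance is undefined; both
weights then fall back to 0.5 on the overlap, with a warning. Weights are
shared across channels.

`mosaic_sequence()` takes the first frame as the base referential, registers
each newcomer against the most recent successfully registered frame,
composes the pairwise homographies onto the chain, grows the canvas to the
union of warped extents, and feather-blends incrementally (current mosaic as
image 1, newcomer as image 2 — the two-image equations applied repeatedly).
Pairwise composition accepts drift over long sequences; global bundle
adjustment is out of scope. Frames that fail registration (fewer than 4
matches or than `min_inliers = 10` consensus points) are skipped with a
warning, never fatally.

## Evaluation

Per image: MAE is the mean of the four absolute coordinate differences
between ground-truth and predicted box (n = 4 coordinates — the reading in
which each term is a single absolute difference); IoU is intersection over
union of the half-open pixel sets. Classes: Successful (IoU > 0.8),
Acceptable (0.6 < IoU ≤ 0.8 — the 0.8 boundary is Acceptable), Failed
(≤ 0.6). Summaries report per-class absolute and relative frequencies with
per-class mean MAE/IoU, and overall mean ± sample (n−1) standard deviation.
A missed detection counts as Failed with IoU 0 but is excluded from MAE
averages (MAE is undefined without a box); the missed count is reported
separately.

## The synthetic world

Real D-Eye footage is private, so the package carries a generator whose
output is the test bed for every stage. A scene is: a near-black surround
(value 8, sensor noise σ = 3); a circular retinal window with red-dominant
base color (195, 95, 45) and a radial falloff to 55% at the rim (soft 2-px
edge); 6% multiplicative band-limited texture (σ = 2.5) standing in for
choroidal mottle — this is what gives the keypoint detector realistic
anchors; a bright optic-disc blob at 0.35 r eccentricity; and dark vessel
curves random-walking outward from the disc with tapering width. Sequences
warp the master scene by seeded similarity transforms (defaults: shift
≤ 30 px, rotation ≤ 5°, scale 1 ± 0.05 — the small-motion regime) and
scale intensities by 1 ± `illum_jitter`, recording boxes and homographies
exactly. Everything is bit-reproducible from the seed.

What a green test does establish: the chain's geometry is right (circles
recovered, homographies within a pixel at the corners, landmarks reprojected
within 2 px through a 5-frame mosaic), its arithmetic is right (oracle
equivalence for IoU/MAE/Otsu/blending), and its failure modes are clean.
What it does not establish: performance on real tissue. The generator has no
specular glints, no motion blur, no partial occlusion by eyelids, no
non-planar parallax — its contrast invariant (inside/outside red-mean ratio
≥ 2) is generous compared to the worst real frames. Numbers measured on this
world say the implementation is faithful, not that a clinic should expect
the same IoU.

## Numerical choices and limitations

- Coordinates are 0-based, origin top-left, boxes half-open; areas are exact
  pixel-set counts. Quantization to 8 bits always rounds half away from
  zero.
- Otsu plateaus take the midpoint; inverting an image complements the mask
  up to pixels exactly at the threshold.
- RANSAC uses R's RNG: seed the session (or pass `--seed` on the CLI) for
  byte-reproducible mosaics. All synthetic generation requires an explicit
  seed.
- The CHT reports integer-resolution centers/radii (sub-pixel circle
  refinement is unnecessary at box-evaluation granularity).
- Video containers are not decoded — frames must be extracted to PGM/PPM
  first; this build reads and writes only dependency-free formats.
- A frame-quality filter is deliberately absent: frames that defeat the
  detector are skipped and logged, not pre-classified.
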