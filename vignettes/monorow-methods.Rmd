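---
title: "Monocular crop-row localization: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monocular crop-row localization: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monorow)
```

## The problem

Automatic row-following in a field — here motivated by righting machines for
rolled ratoon-rice stubble rows — needs the metric 3D position of each crop
row relative to the vehicle. A single RGB camera cannot measure distance by
itself, but two deep models together can: an instance-segmentation model
labels the pixels of each row, and a monocular depth-prediction model assigns
every pixel a metric depth. `monorow` implements everything downstream and
around those two networks: the geometry that fuses their outputs into
navigation lines and row point clouds, the depth-map storage conventions, the
evaluation metrics, the cross-camera calibration of a migrated depth model,
and a synthetic scene generator that stands in for the networks so the whole
pipeline is testable on any machine.

The networks themselves are deliberately out of scope. Any "depth provider" —
a function `(image, s) -> depth_map` — can be plugged in; the package ships a
passthrough provider and a focal-length-biased provider that emulate a
perfect and a migrated model respectively.

## Pinhole geometry

All 3D reasoning uses the standard pinhole model. With pixel focal lengths
$f_x, f_y$ and optical centre $(c_x, c_y)$,

$$u = f_x X/Z + c_x, \qquad v = f_y Y/Z + c_y,$$

where $(X, Y, Z)$ is a camera-frame point in metres (X right, Y down, Z along
the optical axis) and $(u, v)$ its pixel position. Depth throughout the
package is the **Z coordinate** — distance along the optical axis — not the
Euclidean ray length. Pixel coordinates are 0-based, `(u, v)` =
(column, row), and an integer coordinate names a pixel centre; the convention
is stated here once because nothing in the file formats records it.

Two intrinsics transforms matter for cross-camera work:

* uniform resize by $s$ multiplies $f_x, f_y, c_x, c_y$ by $s$ (pixel focal
  length scales with pixel density);
* a centre crop leaves $f_x, f_y$ unchanged and shifts the optical centre by
  the removed border.

Back-projecting a resized image at correspondingly scaled pixel coordinates,
or a cropped image at shifted coordinates, yields identical 3D points — the
invariance the geometry tests assert, and the reason an input-resize
correction (below) is geometrically coherent. Resized pixel dimensions are
rounded to nearest; intrinsics scale by the *requested* factor, not the
post-rounding ratio, since the sub-pixel discrepancy is far below any other
error source in the pipeline.

## Depth-map storage

Depth maps are stored as single-channel 16-bit PNGs holding millimetres
(`round(metres * 1000)`), value 0 meaning "no measurement". Millimetre
quantisation keeps three decimals of precision, so one encode/decode round
trip moves no valid pixel by more than 0.0005 m, and a second round trip is
bit-identical. The representable range at 16 bits is 65.5 m; the package's
default working range is 20 m, matching what field depth cameras are trusted
for. On decode, stored values beyond the working range become *missing*
rather than being clipped: a clipped value would be a fabricated measurement,
which is the wrong failure mode for navigation.

Reading uses the `png` package (lossless for 16-bit input). Writing uses a
small PNG encoder internal to the package, because no pre-installed R writer
emits 16-bit grayscale PNGs; it produces the minimal IHDR/IDAT/IEND chunk
sequence with a zlib-compressed image stream and is exercised by the
round-trip tests above.

## Evaluation metrics

Predictions are scored against a sensor reference only at valid reference
pixels (the mask). With $N$ masked pixels, predictions $y_p$ and references
$y_g$:

* ABS-REL $= \frac{100}{N}\sum |y_p - y_g| / y_g$ (percent);
* RMSE $= \sqrt{\frac1N \sum (y_p - y_g)^2}$ (metres);
* RMSE$_{\log}$ with natural logs;
* SQ-REL $= \frac1N \sum ((y_p - y_g)/y_g)^2$ — the dimensionless ratio
  form, which is invariant under joint rescaling of both maps like the other
  relative metrics (the alternative $(y_p-y_g)^2/y_g$ convention carries
  units of metres and is not);
* threshold accuracies $\delta_n$: the percentage of pixels with
  $\max(y_g/y_p,\, y_p/y_g) < 1.25^n$, strict inequality;
* silog: with $d_i = \log y_{p,i} - \log y_{g,i}$, the default form is the
  **variance** $\frac1N\sum d_i^2 - (\frac1N\sum d_i)^2$, which is exactly
  zero under any constant multiplicative bias — the scale-invariance the
  metric is named for. A variant that adds the squared-mean term instead of
  subtracting it appears in some typeset formulations; it is not
  scale-invariant, and we treat it as a typographical corruption of the
  variance form, while exposing it behind `form = "printed"` so both can be
  compared.

The training-loss counterpart `silog_loss()` is
$\alpha\sqrt{\frac1N\sum d_i^2 - \lambda(\frac1N\sum d_i)^2}$ with defaults
$\lambda = 0.85$, $\alpha = 10$, masked identically (null label pixels never
contribute).

Dataset-level scores are unweighted means of per-image metrics, not pooled
pixels: every image counts equally regardless of how sparse its reference
is. Predictions that are non-positive under a log metric raise an error with
the offending pixel count; dropping them silently would quietly change $N$
between the models being compared.

Chamfer distance between point sets $A, B$ uses the squared bidirectional
mean, $\frac{1}{|A|}\sum_a \min_b \|a-b\|^2 + \frac{1}{|B|}\sum_b \min_a
\|a-b\|^2$, the convention of the point-cloud generation literature; a
non-squared variant is available since published CD tables do not always
state which was used. The nearest-neighbour search is an exact brute-force
scan in C++ — the clouds this package produces are thousands of points,
where a spatial index would cost more than it saves.

## Fusion: navigation points and row clouds

For each row instance, the vertical pixel extent of its mask is split into
`n_bands` (default 14) equal-height horizontal bands; each occupied band
contributes one navigation point at the mean $(u, v)$ of its pixels. Bands
partition the *instance's own* extent, not the full image height: rows at
different distances occupy very different image spans, and per-instance
banding spreads the points along each row's visible length. The per-band
mean is over all mask pixels of the band. Both choices are the natural
reading of "divide the instance mask into n horizontal rows", and both are
isolated in one function should a variant be needed.

Each point then looks up its depth at the nearest pixel (band means are
fractional; exact halves round upward for determinism). Bilinear lookup is
available but not the default because interpolation across the 0-missing
sentinel would blend "no data" into a distance; the implementation falls
back to nearest whenever any of the four neighbours is missing. Points whose
depth is missing or beyond `max_depth` (default 5 m) are dropped: steering
needs near-field distances, and depth accuracy — of sensors and models
alike — degrades with range. Surviving points are back-projected to the
camera frame; the ordered per-instance sequence is the navigation line (no
line fitting or smoothing — the points are connected as they are).

Row point clouds back-project *every* instance pixel with valid depth within
`max_depth`, one cloud per instance.

When a reference depth map accompanies the prediction, the range filter is
applied on the **reference** depth, and image positions where either map is
null are dropped from both sides, so predicted and reference points are
position-matched pairs differing only in depth. The package then reports the
chamfer distance between the pooled navigation-point sets of the image, and
the mean over instances of per-row cloud CDs (clouds are per-row objects, so
per-instance CD is the natural unit; the navigation points of an image form
one line set and are pooled).

## Cross-camera calibration

A depth network trained on one camera systematically mis-scales when shown
another camera's images: raising the pixel focal length of the input shrinks
the predicted depths, and lowering it inflates them. The minimal model of
this behaviour — implemented by the synthetic `biased_provider()` — is

$$\hat y = y \cdot \frac{f_{\mathrm{ref}}}{s \cdot f_{\mathrm{cam}}},$$

where $f_{\mathrm{ref}}$ is the training camera's pixel focal length,
$f_{\mathrm{cam}}$ the deployed one's, and $s$ the input resize factor. Two
corrections invert it:

* **input resize**: feed the model the image enlarged by $s$, pushing the
  effective focal length toward the training value;
* **output scale**: divide the predicted depths by a constant.

Both are found by explicit grid search (defaults: scale 0.25–4.0 step 0.01,
resize 0.5–4.0 step 0.02) minimising ABS-REL on the 0–5 m reference range,
averaged over the calibration pairs. A grid is preferred over continuous
optimisation because the objective is cheap, the answer is needed to about
one grid step, and the search is trivially reproducible. On the ideal
provider the objective is unimodal in the factor and both methods recover
the same value; on real models the two optima need not coincide — the
transforms act at different points of the network's processing, and the
package reports whatever each search finds rather than modelling the
discrepancy. Input-resize results cannot be applied to an existing depth
map (they change what the model is shown), and `apply_depth_scale()` refuses
them with an explanation.

## The synthetic scene

`render_scene()` models the data-collection rig: a camera `camera_height`
above a flat ground plane, pitched down by `pitch`, seeing parallel row
strips of width `row_width` at spacing `row_spacing`. Depth is the
closed-form ray/plane intersection
$Z(v) = h / (d_y \cos\theta + \sin\theta)$ with $d_y = (v - c_y)/f_y$;
pixels above the horizon or beyond `max_range` are missing. Defaults — a
320×180 camera with 150 px focal length, 1.2 m height, 0.35 rad pitch, four
0.45 m-wide rows at 0.8 m spacing — describe a small navigation camera on a
paddy vehicle over typical row geometry, and put roughly a third of the
image inside the 5 m navigation range. Sizes were chosen so the full test
suite and the acceptance script run in well under a minute of simulation
time while every cloud still holds thousands of points.

Sensor corruption is multiplicative lognormal noise (depth error grows with
range; depths stay positive) plus spatially uniform dropout. Real stereo
dropout is structured — it hugs edges and low-texture regions — but no
downstream contract depends on *where* pixels are missing, so uniform
dropout exercises the same code paths. Rows are flat strips without height
relief for the same reason.

What passing tests on this scene do show: the geometry, banding, filtering,
metric and calibration code is correct to the stated tolerances, end to end.
What they do not show: robustness to segmentation errors, structured
dropout, non-planar ground, or a real network's non-multiplicative biases.
The ground-truth navigation points of a scene are computed by an independent
closed-form path (no code shared with the fusion pipeline), which is what
makes the end-to-end zero-error test evidence rather than tautology.

## Numerical choices and degenerate inputs

* Millimetre quantisation rounds to nearest; decode errors are ≤ 0.5 mm.
* Nearest-pixel depth lookup breaks half-pixel ties upward.
* An instance shorter than `n_bands` rows yields fewer points (empty bands
  are skipped, never interpolated).
* A mask with no instances fuses to an empty result with a warning — a
  valid field state (no rows in view), not an error.
* An instance whose pixels all lack valid depth yields an empty cloud
  flagged `empty`; chamfer distance on an empty cloud is an error, because
  it means upstream filtering removed everything and the comparison is
  meaningless.
* Calibration grids must be positive and non-empty; an objective with no
  valid reference pixels is an error, not an NA.
* All randomness (corruption, provider noise) flows through explicit seeds
  and restores the caller's RNG state.

## Worked example

```{r example, eval = FALSE}
cfg <- scene_config()
sc <- render_scene(cfg)

# a depth model migrated from a camera with 1.94x the pixel focal length
prov <- biased_provider(cfg, f_ref_over_f_cam = 1.94,
                        noise = corruption_config(noise_sigma = 0.02, seed = 1))
pairs <- list(list(image = NULL, label = sc$depth))

cal <- calibrate_output_scale(prov, pairs)
cal$factor                      # recovers ~1.94

pred <- apply_depth_scale(prov(s = 1), cal)
res <- fuse(sc$masks, pred, sc$camera, fusion_config(),
            depth_label = sc$depth)
res$cd_navigation               # small; 0 for a perfect prediction
```

`scripts/acceptance.R` runs exactly this study — plus the geometry and
encoding round trips — from scratch and writes every quantity to JSON.

## Known limitations

* Fusion quality is bounded by the instance masks; segmentation failure
  modes are not modelled.
* No lens distortion, extrinsics or world frame: everything lives in the
  camera frame of a single pinhole view.
* The chamfer search is exact brute force; clouds beyond ~10⁵ points would
  want a spatial index.
* The biased provider is the *minimal* migration model; real networks add
  range-dependent and scene-dependent structure that a single scalar cannot
  capture, which is why the two calibration optima can differ in practice.
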