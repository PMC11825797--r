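# monorow

Monocular recognition-and-localization of crop rows for field navigation.

A vehicle that follows crop rows — the motivating case is a righting machine
for rolled ratoon-rice stubble rows — needs each row's metric 3D position
relative to the camera. `monorow` obtains it from a *single* RGB camera by
fusing the outputs of two models: an instance-segmentation model that labels
each row's pixels, and a monocular depth-prediction model that assigns every
pixel a distance. The networks themselves are pluggable black boxes; this
package provides everything around them, fully tested:

* **Pinhole geometry** — projection/back-projection
  (`u = f_x X/Z + c_x`, `v = f_y Y/Z + c_y`), plus the intrinsics
  transforms for image resizing (scales the pixel focal length) and centre
  cropping (shifts only the optical centre).
* **Depth I/O** — 16-bit single-channel PNGs holding millimetres, 0 =
  missing, 20 m default range; decode reproduces every valid pixel within
  0.0005 m.
* **Metrics** — the eight masked depth metrics (ABS-REL, RMSE, silog,
  δ₁/δ₂/δ₃, RMSE_log, SQ-REL), the silog training loss, and chamfer
  distance between point clouds.
* **Fusion** — each row mask's vertical extent is split into 14 horizontal
  bands; each occupied band's mean (u, v) becomes a navigation point, takes
  its depth from the depth map, is filtered to the 0–5 m near field, and is
  back-projected to the camera frame. The ordered points form the
  navigation line; all mask pixels with valid near-field depth form the
  per-row 3D point cloud.
* **Cross-camera calibration** — a depth model migrated to a camera with a
  different pixel focal length mis-scales its output
  (`pred ≈ true · f_ref / (s · f_cam)`). Grid search recovers either the
  input-resize factor `s` or the output-scale divisor that minimises
  ABS-REL on a calibration set.
* **Synthetic scenes** — closed-form ground-plane rendering of a pitched
  camera over parallel row strips, sensor corruption (lognormal noise,
  dropout), and biased "model" providers, so the entire pipeline runs and
  is validated without any trained network, GPU or download.

## Worked example

Calibrate a migrated depth model on a synthetic field scene, then localize
the rows:

```r
library(monorow)

cfg <- scene_config()          # 320x180 camera, 1.2 m high, 20° down, 4 rows
sc  <- render_scene(cfg)
sc$depth
#> depth_map: 320x180 px, 75.0% valid, range 1.328-18.687 m (max_range 20)
sc$masks
#> instance_masks: 320x180 px, 4 instance(s) [1, 2, 3, 4]

# a depth model trained at 1.94x this camera's pixel focal length,
# with 2% multiplicative measurement noise
prov  <- biased_provider(cfg, f_ref_over_f_cam = 1.94,
                         noise = corruption_config(noise_sigma = 0.02, seed = 1))
pairs <- list(list(image = NULL, label = sc$depth))

cal <- calibrate_output_scale(prov, pairs)
cal
#> calibration_result (output_scale): factor 1.94, abs_rel = 1.59478 over 376 grid point(s)

pred <- apply_depth_scale(prov(s = 1), cal)
evaluate_depth(depth_pair(unclass(pred), unclass(sc$depth), max_depth = 5))
#> ABS-REL%  RMSE(m)   Silog  delta1%  delta2%  delta3%  RMSElog  SQ-REL
#>     1.59    0.051  0.0004   100.00   100.00   100.00   0.0200  0.0004

res <- fuse(sc$masks, pred, sc$camera, fusion_config(), depth_label = sc$depth)
res
#> fusion_result: 44 navigation point(s), 4 row cloud(s)
#>   chamfer distance: navigation points 0.00681903, row clouds 0.00102174
```

Reading the output: the grid search recovered the construction bias (1.94)
exactly; after correction the near-field (≤ 5 m) absolute relative depth
error is 1.6 % — the residual measurement noise — and every pixel is within
the δ₁ ratio threshold. The 44 navigation points (up to 14 per row, fewer
where a row exits the 5 m range) sit within a few millimetres of the
reference line, and the per-row clouds agree to ~0.001 in squared-mean
chamfer distance. Uncorrected, the same provider's ABS-REL is 94 % and the
navigation-point chamfer distance is about 5.8 — the migration failure the
calibration removes.

A command-line front end wraps the same pipeline
(`inst/scripts/monorow simulate | fuse | evaluate | calibrate`); see
`?monorow_cli`.

## Documentation

The methods vignette (`vignettes/monorow-methods.Rmd`) explains the model
and its assumptions, every tunable parameter with units and defaults, what
the synthetic scenes do and do not emulate, and the package's numerical
conventions and design decisions.
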