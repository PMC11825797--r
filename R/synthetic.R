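#' Configuration of a synthetic field scene
#'
#' Describes a camera mounted on a vehicle, tilted down toward a flat
#' ground plane carrying parallel crop-row strips — the geometry of a
#' field-navigation rig. Defaults model a small forward-facing navigation
#' camera: 320x180 px with 150 px focal length (about 94 degrees horizontal
#' field of view), mounted 1.2 m above ground and pitched 0.35 rad
#' (about 20 degrees) downward; four rows 0.45 m wide at 0.8 m spacing,
#' typical of paddy rows.
#'
#' @param camera A [camera_intrinsics] (default the 320x180 camera above).
#' @param camera_height Camera height above the ground plane (m).
#' @param pitch Downward tilt of the optical axis (radians, in `(0, pi/2)`;
#'   `pi/2` looks straight down).
#' @param n_rows Number of parallel row strips.
#' @param row_spacing Centre-to-centre row spacing (m), `> row_width`.
#' @param row_width Strip width (m), `> 0`.
#' @param row_length Strip length along the forward direction (m), starting
#'   at the camera's ground foot.
#' @param max_range Depth beyond which pixels are recorded as missing (m).
#' @return A `scene_config` list.
#' @export
scene_config <- function(camera = camera_intrinsics(150, 150, 159.5, 89.5, 320, 180),
                         camera_height = 1.2, pitch = 0.35,
                         n_rows = 4L, row_spacing = 0.8, row_width = 0.45,
                         row_length = 30, max_range = 20) {
  stopifnot(inherits(camera, "camera_intrinsics"))
  if (camera_height <= 0) stop("camera_height must be positive")
  if (pitch <= 0 || pitch >= pi / 2)
    stop("pitch must lie strictly between 0 and pi/2 radians")
  n_rows <- as.integer(n_rows)
  if (n_rows < 1L) stop("n_rows must be at least 1")
  if (!(row_spacing > row_width && row_width > 0))
    stop("need row_spacing > row_width > 0")
  structure(list(camera = camera, camera_height = camera_height, pitch = pitch,
                 n_rows = n_rows, row_spacing = row_spacing,
                 row_width = row_width, row_length = row_length,
                 max_range = max_range),
            class = "scene_config")
}

#' Sensor corruption model for synthetic depth
#'
#' Emulates the two dominant defects of field depth maps: null regions
#' (stereo dropout) and range-dependent measurement noise. Noise is
#' multiplicative lognormal — depth errors grow with distance and depths
#' stay positive — and dropout zeroes a uniform random fraction of valid
#' pixels.
#'
#' @param dropout_rate Fraction of valid pixels set to missing, in `[0, 1)`.
#' @param noise_sigma Lognormal sigma of the multiplicative noise, `>= 0`.
#' @param max_range Depths pushed beyond this by noise become missing (m).
#' @param seed Integer seed; corruption is fully reproducible.
#' @return A `corruption_config` list.
#' @export
corruption_config <- function(dropout_rate = 0, noise_sigma = 0,
                              max_range = 20, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(dropout_rate = dropout_rate, noise_sigma = noise_sigma,
                 max_range = max_range, seed = as.integer(seed)),
            class = "corruption_config")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# closed-form ray/ground-plane geometry -------------------------------------
# Camera frame: X right, Y down, Z optical axis. The camera sits
# camera_height above a horizontal plane and is pitched down by `pitch`.
# For pixel (u, v): dy = (v - cy)/fy, dx = (u - cx)/fx; the depth along the
# optical axis where the ray meets the plane is
#   Z = camera_height / (dy * cos(pitch) + sin(pitch)),
# positive only below the horizon. Ground coordinates of the hit point:
# lateral x_g = Z * dx, forward z_g = Z * (cos(pitch) - dy * sin(pitch)).

scene_depth_at <- function(cfg, v) {
  dy <- (v - cfg$camera$cy) / cfg$camera$fy
  den <- dy * cos(cfg$pitch) + sin(cfg$pitch)
  ifelse(den > 1e-12, cfg$camera_height / den, 0)
}

scene_ground_at <- function(cfg, u, v) {
  z <- scene_depth_at(cfg, v)
  dx <- (u - cfg$camera$cx) / cfg$camera$fx
  dy <- (v - cfg$camera$cy) / cfg$camera$fy
  list(z = z, lateral = z * dx, forward = z * (cos(cfg$pitch) - dy * sin(cfg$pitch)))
}

scene_row_centres <- function(cfg) {
  (seq_len(cfg$n_rows) - (cfg$n_rows + 1) / 2) * cfg$row_spacing
}

#' Render a synthetic field scene
#'
#' Produces the analytic depth map of the ground plane seen by the tilted
#' camera (depth = distance along the optical axis; pixels above the horizon
#' or beyond `max_range` are missing), an instance mask with one id per row
#' strip, and ground-truth navigation points computed directly from the
#' scene's closed-form geometry (banded means of the strip pixels, depth
#' from the analytic ground-plane formula) for end-to-end checks.
#'
#' @param cfg A [scene_config].
#' @param n_bands Band count used for the ground-truth navigation points.
#' @param nav_max_depth Depth filter for the ground-truth points (m).
#' @return A list with elements `depth` ([depth_map]), `masks`
#'   ([instance_masks]), `gt_points` (data frame as from
#'   [to_camera_frame()]), and `camera`.
#' @export
render_scene <- function(cfg, n_bands = 14L, nav_max_depth = 5) {
  stopifnot(inherits(cfg, "scene_config"))
  k <- cfg$camera
  u <- seq_len(k$width) - 1
  v <- seq_len(k$height) - 1
  g <- scene_ground_at(cfg, rep(u, each = k$height),
                       rep(v, times = k$width))
  z <- matrix(g$z, k$height, k$width)
  lat <- matrix(g$lateral, k$height, k$width)
  fwd <- matrix(g$forward, k$height, k$width)
  visible <- z > 0 & z <= cfg$max_range
  if (!any(visible))
    stop("pitch/height leave no ground pixel within max_range")
  z[!visible] <- 0

  labels <- matrix(0L, k$height, k$width)
  centres <- scene_row_centres(cfg)
  for (i in seq_along(centres)) {
    inrow <- visible &
      abs(lat - centres[i]) <= cfg$row_width / 2 &
      fwd >= 0 & fwd <= cfg$row_length
    labels[inrow] <- i
  }

  gt <- scene_navigation_points(cfg, labels, n_bands = n_bands,
                                nav_max_depth = nav_max_depth)
  list(depth = depth_map(z, max_range = cfg$max_range),
       masks = instance_masks(labels),
       gt_points = gt,
       camera = k)
}

# Ground-truth navigation points straight from the analytic geometry:
# banded pixel means as in the fusion contract, but with depth evaluated
# from the closed-form plane formula at the nearest pixel row and the
# back-projection written out explicitly. Shares no code with fusion.
scene_navigation_points <- function(cfg, labels, n_bands = 14L,
                                    nav_max_depth = 5) {
  k <- cfg$camera
  ids <- sort(unique(labels[labels > 0L]))
  rows <- list()
  for (id in ids) {
    px <- which(labels == id, arr.ind = TRUE)
    v <- px[, 1] - 1; u <- px[, 2] - 1
    v_min <- min(v); extent <- max(v) - v_min + 1
    band <- pmin(n_bands - 1L, as.integer(floor((v - v_min) * n_bands / extent)))
    for (b in sort(unique(band))) {
      mu <- mean(u[band == b]); mv <- mean(v[band == b])
      z <- scene_depth_at(cfg, floor(mv + 0.5))  # nearest pixel row
      if (z <= 0 || z > nav_max_depth) next
      rows[[length(rows) + 1L]] <- data.frame(
        instance_id = id, band = b, u = mu, v = mv, depth = z,
        x = (mu - k$cx) * z / k$fx, y = (mv - k$cy) * z / k$fy, z = z)
    }
  }
  if (!length(rows))
    return(data.frame(instance_id = integer(), band = integer(), u = numeric(),
                      v = numeric(), depth = numeric(), x = numeric(),
                      y = numeric(), z = numeric()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Apply sensor corruption to a depth map
#'
#' Valid depths are multiplied by lognormal noise, a `dropout_rate` fraction
#' of them is zeroed uniformly at random, and values pushed beyond
#' `max_range` become missing. Deterministic for a fixed seed; the caller's
#' RNG state is untouched.
#'
#' @param depth A [depth_map].
#' @param corruption A [corruption_config].
#' @return A corrupted [depth_map].
#' @export
corrupt_depth <- function(depth, corruption) {
  stopifnot(inherits(depth, "depth_map"), inherits(corruption, "corruption_config"))
  d <- unclass(depth)
  with_seed(corruption$seed, {
    valid <- which(d > 0)
    if (corruption$noise_sigma > 0 && length(valid))
      d[valid] <- d[valid] *
        exp(stats::rnorm(length(valid), 0, corruption$noise_sigma))
    if (corruption$dropout_rate > 0 && length(valid)) {
      n_drop <- round(corruption$dropout_rate * length(valid))
      d[sample(valid, n_drop)] <- 0
    }
  })
  d[d > corruption$max_range] <- 0
  depth_map(d, max_range = corruption$max_range)
}

#' A focal-length-biased synthetic depth provider
#'
#' Builds a depth-provider function emulating how a depth network trained at
#' one camera's pixel focal length responds to another camera: the predicted
#' depth equals the true depth multiplied by `f_ref_over_f_cam / s`, where
#' `s` is the input resize factor. Enlarging the input (raising the pixel
#' focal length) therefore shrinks the predictions — the minimal model of
#' the cross-camera migration failure, and the mechanism both calibration
#' corrections invert: resizing the input by `s = f_ref_over_f_cam` or
#' dividing the output by the same factor cancels the bias exactly.
#'
#' @param scene A [scene_config] the provider renders its "predictions" of.
#' @param f_ref_over_f_cam Ratio of the training camera's pixel focal length
#'   to the deployed camera's, `> 0` (1 = no bias).
#' @param noise Optional [corruption_config] applied to each prediction;
#'   the corruption seed is combined with `s` so repeated calls with the
#'   same arguments are identical.
#' @return A function `provider(image, s = 1)` returning a [depth_map] at
#'   the s-resized resolution. The `image` argument is accepted for
#'   interface compatibility and ignored: the provider predicts from scene
#'   truth.
#' @export
biased_provider <- function(scene, f_ref_over_f_cam = 1, noise = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  if (f_ref_over_f_cam <= 0) stop("f_ref_over_f_cam must be positive")
  if (!is.null(noise)) stopifnot(inherits(noise, "corruption_config"))
  force(scene); force(f_ref_over_f_cam)
  function(image = NULL, s = 1) {
    k2 <- intrinsics_resize(scene$camera, s)
    cfg2 <- scene
    cfg2$camera <- k2
    u <- seq_len(k2$width) - 1
    v <- seq_len(k2$height) - 1
    z <- matrix(scene_depth_at(cfg2, rep(v, times = k2$width)),
                k2$height, k2$width)
    z[z <= 0 | z > scene$max_range] <- 0
    pred <- z * f_ref_over_f_cam / s
    d <- depth_map(pred, max_range = Inf)
    if (!is.null(noise)) {
      nz <- noise
      nz$seed <- noise$seed + as.integer(round(1000 * s)) %% 100000L
      nz$max_range <- Inf
      d <- corrupt_depth(d, nz)
    }
    d
  }
}

#' A passthrough depth provider
#'
#' Returns the scene's true depth at the requested resolution — a perfect
#' "model", useful as the zero-error baseline in end-to-end tests.
#'
#' @param scene A [scene_config].
#' @return A function `provider(image, s = 1)` returning a [depth_map].
#' @export
passthrough_provider <- function(scene) {
  biased_provider(scene, f_ref_over_f_cam = 1, noise = NULL)
}

#' Write a scene fixture set to disk
#'
#' Writes the file layout the I/O helpers expect, paired by a shared stem:
#' `<stem>.png` (8-bit RGB placeholder), `<stem>_depth.png` (16-bit label
#' depth), `<stem>_pred.png` (16-bit predicted depth, if a provider is
#' given), `<stem>_mask.png` (label mask), `<stem>_intrinsics.json` and
#' `<stem>_navigation.json` (ground-truth navigation points).
#'
#' @param scene A [scene_config].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem, default `"scene"`.
#' @param corruption Optional [corruption_config] applied to the label
#'   depth before writing.
#' @param provider Optional provider function whose `s = 1` output is
#'   written as the predicted depth (values clipped at the 20 m encoding
#'   range).
#' @return The stem path, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene", corruption = NULL,
                        provider = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- render_scene(scene)
  stem_path <- file.path(dir, stem)
  d <- sc$depth
  if (!is.null(corruption)) d <- corrupt_depth(d, corruption)
  write_depth_png(d, paste0(stem_path, "_depth.png"))
  write_mask_png(sc$masks, paste0(stem_path, "_mask.png"))
  write_intrinsics(sc$camera, paste0(stem_path, "_intrinsics.json"))
  write_navigation_json(sc$gt_points, paste0(stem_path, "_navigation.json"))
  # RGB placeholder: rows shaded by instance id so the file is a viewable image
  rgb <- array(0.15, dim = c(nrow(sc$masks), ncol(sc$masks), 3))
  lab <- unclass(sc$masks)
  rgb[, , 2] <- 0.2 + 0.6 * (lab > 0)
  rgb[, , 1][lab > 0] <- 0.2 + 0.1 * lab[lab > 0]
  png::writePNG(rgb, paste0(stem_path, ".png"))
  if (!is.null(provider)) {
    p <- provider(s = 1)
    pv <- pmin(unclass(p), 20)
    write_depth_png(depth_map(pv, max_range = 20),
                    paste0(stem_path, "_pred.png"))
  }
  invisible(stem_path)
}
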