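#' Configuration of the mask/depth fusion pipeline
#'
#' @param n_bands Number of equal-height horizontal bands each instance's
#'   vertical extent is split into (default 14).
#' @param max_depth Navigation depth filter in metres (default 5): points
#'   and cloud pixels beyond it are discarded, since near-field distance is
#'   what steering needs and depth accuracy degrades with range.
#' @param depth_lookup How a fractional navigation point samples the depth
#'   map: `"nearest"` (default) or `"bilinear"`. Bilinear interpolates
#'   across the four neighbouring pixels and falls back to nearest whenever
#'   any of them is missing, so the 0-sentinel is never blended into a value.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(n_bands = 14L, max_depth = 5,
                          depth_lookup = c("nearest", "bilinear")) {
  n_bands <- as.integer(n_bands)
  if (n_bands < 1L) stop("n_bands must be at least 1")
  if (!is.numeric(max_depth) || max_depth <= 0) stop("max_depth must be positive")
  structure(list(n_bands = n_bands, max_depth = max_depth,
                 depth_lookup = match.arg(depth_lookup)),
            class = "fusion_config")
}

#' Extract 2D navigation points from instance masks
#'
#' Each instance's vertical pixel extent is divided into `n_bands`
#' equal-height horizontal bands; every band containing at least one
#' instance pixel yields one navigation point at the mean (u, v) of that
#' band's pixels. Bands that receive no pixel (possible when an instance is
#' shorter than `n_bands` rows) are skipped. Within an instance, points are
#' ordered by band from the image top; connected in order they form the
#' navigation line of that crop row.
#'
#' @param masks An [instance_masks] object.
#' @param cfg A [fusion_config].
#' @param ids Instances to process (default: all present). An id absent
#'   from the label grid is an error.
#' @return A data frame with columns `instance_id`, `band` (0-based),
#'   `u`, `v` (0-based pixel coordinates, fractional).
#' @export
extract_navigation_points <- function(masks, cfg = fusion_config(), ids = NULL) {
  stopifnot(inherits(masks, "instance_masks"), inherits(cfg, "fusion_config"))
  present <- instance_ids(masks)
  if (is.null(ids)) ids <- present
  missing_ids <- setdiff(ids, present)
  if (length(missing_ids))
    stop("instance id(s) absent from label grid: ",
         paste(missing_ids, collapse = ", "))
  if (length(ids) == 0L)
    return(data.frame(instance_id = integer(), band = integer(),
                      u = numeric(), v = numeric()))
  out <- lapply(ids, function(id) {
    px <- which(unclass(masks) == id, arr.ind = TRUE)
    v <- px[, 1] - 1  # 0-based row = v
    u <- px[, 2] - 1
    v_min <- min(v); v_max <- max(v)
    extent <- v_max - v_min + 1
    band <- pmin(cfg$n_bands - 1L,
                 as.integer(floor((v - v_min) * cfg$n_bands / extent)))
    occupied <- sort(unique(band))
    data.frame(
      instance_id = id,
      band = occupied,
      u = vapply(occupied, function(b) mean(u[band == b]), numeric(1)),
      v = vapply(occupied, function(b) mean(v[band == b]), numeric(1)))
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(instance_id = integer(), band = integer(),
                      u = numeric(), v = numeric())
  out
}

# depth at fractional (u, v); 0 where missing / out of image
lookup_depth <- function(depth, u, v, method = "nearest") {
  d <- unclass(depth)
  h <- nrow(d); w <- ncol(d)
  # nearest pixel, ties broken upward for determinism (band means are
  # often exact .5 fractions)
  ci <- pmin(pmax(floor(u + 0.5), 0), w - 1) + 1
  ri <- pmin(pmax(floor(v + 0.5), 0), h - 1) + 1
  near <- d[cbind(ri, ci)]
  if (method == "nearest") return(near)
  # bilinear over the 4 surrounding pixel centres
  u0 <- pmin(pmax(floor(u), 0), w - 1); v0 <- pmin(pmax(floor(v), 0), h - 1)
  u1 <- pmin(u0 + 1, w - 1); v1 <- pmin(v0 + 1, h - 1)
  fu <- u - u0; fv <- v - v0
  q00 <- d[cbind(v0 + 1, u0 + 1)]; q01 <- d[cbind(v0 + 1, u1 + 1)]
  q10 <- d[cbind(v1 + 1, u0 + 1)]; q11 <- d[cbind(v1 + 1, u1 + 1)]
  bil <- (1 - fv) * ((1 - fu) * q00 + fu * q01) +
         fv * ((1 - fu) * q10 + fu * q11)
  ok <- q00 > 0 & q01 > 0 & q10 > 0 & q11 > 0
  ifelse(ok, bil, near)
}

#' Attach depths to navigation points and filter
#'
#' Looks up each point's depth at its (fractional) image position and drops
#' points whose depth is missing (0) or beyond `cfg$max_depth` — the
#' near-field filter of the navigation use case.
#'
#' @param points Data frame from [extract_navigation_points()].
#' @param depth A [depth_map] with the same shape as the mask image.
#' @param cfg A [fusion_config].
#' @return `points` with a `depth` column, filtered.
#' @export
attach_depth <- function(points, depth, cfg = fusion_config()) {
  stopifnot(inherits(depth, "depth_map"), inherits(cfg, "fusion_config"))
  if (nrow(points) == 0L) {
    points$depth <- numeric(0)
    return(points)
  }
  points$depth <- lookup_depth(depth, points$u, points$v, cfg$depth_lookup)
  points[points$depth > 0 & points$depth <= cfg$max_depth, , drop = FALSE]
}

#' Back-project navigation points to the camera frame
#'
#' @param points Data frame with `u`, `v`, `depth` columns (all depths
#'   positive; filter first with [attach_depth()]).
#' @param k A [camera_intrinsics].
#' @return `points` with `x`, `y`, `z` columns (metres, camera frame);
#'   ordering and instance grouping preserved.
#' @export
to_camera_frame <- function(points, k) {
  if (nrow(points) == 0L) {
    points$x <- points$y <- points$z <- numeric(0)
    return(points)
  }
  xyz <- backproject_pixels(cbind(points$u, points$v), points$depth, k)
  points$x <- xyz[, 1]; points$y <- xyz[, 2]; points$z <- xyz[, 3]
  points
}

#' Per-instance 3D point clouds of crop rows
#'
#' Back-projects every instance-mask pixel whose depth is valid and within
#' `cfg$max_depth`, producing one camera-frame cloud per row instance.
#'
#' @param masks An [instance_masks].
#' @param depth A [depth_map] supplying each pixel's depth.
#' @param k A [camera_intrinsics].
#' @param cfg A [fusion_config].
#' @param filter_depth Optional [depth_map] used for the validity/range
#'   filter instead of `depth` itself (e.g. filter by the reference depth
#'   while back-projecting predicted depths at the same pixels).
#' @return A named list (names = instance ids) of `n x 3` matrices; an
#'   instance with no valid pixel yields a `0 x 3` matrix with attribute
#'   `empty = TRUE`.
#' @export
row_point_clouds <- function(masks, depth, k, cfg = fusion_config(),
                             filter_depth = NULL) {
  stopifnot(inherits(masks, "instance_masks"), inherits(depth, "depth_map"))
  if (!all(dim(masks) == dim(depth))) stop("mask and depth shapes differ")
  fd <- if (is.null(filter_depth)) depth else filter_depth
  ids <- instance_ids(masks)
  keep <- unclass(fd) > 0 & unclass(fd) <= cfg$max_depth & unclass(depth) > 0
  out <- lapply(ids, function(id) {
    px <- which(unclass(masks) == id & keep, arr.ind = TRUE)
    if (nrow(px) == 0L) {
      cloud <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
      attr(cloud, "empty") <- TRUE
      return(cloud)
    }
    uv <- cbind(px[, 2] - 1, px[, 1] - 1)
    backproject_pixels(uv, unclass(depth)[px], k)
  })
  names(out) <- ids
  out
}

#' Fuse instance masks and depth into navigation lines and row clouds
#'
#' The full pipeline: banded navigation points from the masks, depth
#' attachment and near-field filtering, back-projection to 3D, and
#' per-instance row clouds. When a reference ("label") depth map is
#' supplied, reference-based points and clouds are produced at the same
#' image positions — the range filter is then applied on the reference
#' depth, and positions where either map is null are dropped from both
#' sides so predicted and reference points stay position-matched — and the
#' chamfer distances between the two navigation-point sets (pooled over the
#' image) and between per-row clouds (averaged over instances) are reported.
#'
#' @param masks An [instance_masks].
#' @param depth_pred Predicted [depth_map].
#' @param k A [camera_intrinsics].
#' @param cfg A [fusion_config].
#' @param depth_label Optional reference [depth_map].
#' @return A `fusion_result` list: `points` (predicted navigation points
#'   with 3D coordinates), `clouds` (per-instance matrices), and when a
#'   label is given also `points_label`, `clouds_label`, `cd_navigation`,
#'   `cd_row_clouds` (mean over instances with both clouds non-empty) and
#'   `cd_row_clouds_per_instance`.
#' @export
fuse <- function(masks, depth_pred, k, cfg = fusion_config(),
                 depth_label = NULL) {
  stopifnot(inherits(masks, "instance_masks"), inherits(depth_pred, "depth_map"),
            inherits(k, "camera_intrinsics"), inherits(cfg, "fusion_config"))
  if (!all(dim(masks) == dim(depth_pred)))
    stop("mask and depth shapes differ")
  if (length(instance_ids(masks)) == 0L)
    warning("no instances in mask image; returning empty result")
  pts2d <- extract_navigation_points(masks, cfg)
  res <- list(config = cfg)

  if (is.null(depth_label)) {
    pts <- attach_depth(pts2d, depth_pred, cfg)
    res$points <- to_camera_frame(pts, k)
    res$clouds <- row_point_clouds(masks, depth_pred, k, cfg)
    class(res) <- "fusion_result"
    return(res)
  }

  if (!all(dim(depth_label) == dim(depth_pred)))
    stop("label and predicted depth shapes differ")
  # filter on the reference depth; keep positions valid in both maps
  lab <- attach_depth(pts2d, depth_label, cfg)
  pred_d <- if (nrow(lab)) lookup_depth(depth_pred, lab$u, lab$v, cfg$depth_lookup) else numeric(0)
  ok <- pred_d > 0
  lab <- lab[ok, , drop = FALSE]
  pred <- lab
  pred$depth <- pred_d[ok]
  res$points <- to_camera_frame(pred, k)
  res$points_label <- to_camera_frame(lab, k)
  res$clouds <- row_point_clouds(masks, depth_pred, k, cfg,
                                 filter_depth = depth_label)
  res$clouds_label <- row_point_clouds(masks, depth_label, k, cfg)

  res$cd_navigation <- if (nrow(res$points) && nrow(res$points_label)) {
    chamfer_distance(as.matrix(res$points[, c("x", "y", "z")]),
                     as.matrix(res$points_label[, c("x", "y", "z")]))
  } else NA_real_
  per_inst <- mapply(function(a, b) {
    if (nrow(a) && nrow(b)) chamfer_distance(a, b) else NA_real_
  }, res$clouds, res$clouds_label)
  res$cd_row_clouds_per_instance <- per_inst
  res$cd_row_clouds <- if (any(!is.na(per_inst))) mean(per_inst, na.rm = TRUE) else NA_real_
  class(res) <- "fusion_result"
  res
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("fusion_result: %d navigation point(s), %d row cloud(s)\n",
              nrow(x$points), length(x$clouds)))
  if (!is.null(x$cd_navigation))
    cat(sprintf("  chamfer distance: navigation points %.6g, row clouds %.6g\n",
                x$cd_navigation, x$cd_row_clouds))
  invisible(x)
}

#' Write navigation points as JSON records
#'
#' One record per point with fields `instance_id`, `band`, `u`, `v`,
#' `depth`, `x`, `y`, `z`.
#'
#' @param points Data frame from [fuse()] / [to_camera_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_navigation_json <- function(points, path) {
  jsonlite::write_json(points, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a point cloud as ASCII XYZ or PLY
#'
#' `write_xyz()` writes one "x y z" line per point (metres);
#' `write_ply()` writes an ASCII PLY header plus the same vertex list.
#'
#' @param cloud An `n x 3` numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  cloud <- as.matrix(cloud)
  utils::write.table(format(cloud, trim = TRUE, scientific = FALSE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_ply <- function(cloud, path) {
  cloud <- as.matrix(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(cloud)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  if (nrow(cloud))
    writeLines(apply(format(cloud, trim = TRUE, scientific = FALSE), 1, paste,
                     collapse = " "), con)
  invisible(path)
}
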