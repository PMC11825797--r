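#' Camera intrinsics for the pinhole model
#'
#' Bundles the pixel-represented focal lengths, the optical centre and the
#' image size of a pinhole camera. The projection model is
#' \deqn{u = f_x X / Z + c_x, \qquad v = f_y Y / Z + c_y,}
#' with \eqn{(X, Y, Z)} in metres in the camera frame (Z along the optical
#' axis, X right, Y down) and \eqn{(u, v)} in pixels.
#'
#' Pixel coordinates are 0-based and `(u, v) = (column, row)`; an integer
#' coordinate refers to the centre of that pixel.
#'
#' @param fx,fy Pixel-represented focal lengths (px), `> 0`.
#' @param cx,cy Optical centre (px), inside the image.
#' @param width,height Image size in pixels, `>= 1`.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' k <- camera_intrinsics(fx = 500, fy = 500, cx = 320, cy = 180,
#'                        width = 640, height = 360)
#' project_points(c(1, 0.5, 2), k)
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(is.numeric(fx), is.numeric(fy), is.numeric(cx), is.numeric(cy))
  if (!(fx > 0 && fy > 0)) stop("focal lengths fx, fy must be positive")
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("image size must be at least 1x1")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("optical centre (cx, cy) must lie inside the image")
  structure(
    list(fx = as.numeric(fx), fy = as.numeric(fy),
         cx = as.numeric(cx), cy = as.numeric(cy),
         width = width, height = height),
    class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: %dx%d px, fx=%.4g fy=%.4g, centre (%.4g, %.4g)\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Project camera-frame points to pixel coordinates
#'
#' Applies the pinhole projection to 3D points in the camera coordinate
#' system. Points behind the camera (`Z <= 0`) are rejected: depth here is
#' the distance along the optical axis, which must be positive for anything
#' the camera can see.
#'
#' @param xyz A numeric vector of length 3 or an `n x 3` matrix of camera
#'   frame coordinates in metres (columns X, Y, Z).
#' @param k A [camera_intrinsics] object.
#' @return A data frame with columns `u`, `v` (px, possibly fractional) and
#'   `depth` (metres, equal to the input Z).
#' @seealso [backproject_pixels()] for the inverse.
#' @export
project_points <- function(xyz, k) {
  stopifnot(inherits(k, "camera_intrinsics"))
  xyz <- to_xyz_matrix(xyz)
  z <- xyz[, 3]
  if (any(!is.finite(z)) || any(z <= 0))
    stop("cannot project points with non-positive Z (behind the camera)")
  data.frame(
    u = k$fx * xyz[, 1] / z + k$cx,
    v = k$fy * xyz[, 2] / z + k$cy,
    depth = z)
}

#' Back-project pixels with known depth to camera-frame points
#'
#' Inverts the pinhole projection: a pixel `(u, v)` with depth `Z` maps to
#' \eqn{X = (u - c_x) Z / f_x}, \eqn{Y = (v - c_y) Z / f_y}. Zero or
#' negative depths are rejected rather than silently dropped, because 0
#' encodes a missing measurement and must be filtered before geometry.
#'
#' @param uv A numeric vector `c(u, v)` or an `n x 2` matrix of pixel
#'   coordinates (0-based, column/row).
#' @param depth Depth in metres along the optical axis; length 1 or `n`.
#' @param k A [camera_intrinsics] object.
#' @return An `n x 3` numeric matrix with columns `x`, `y`, `z` (metres).
#' @export
backproject_pixels <- function(uv, depth, k) {
  stopifnot(inherits(k, "camera_intrinsics"))
  if (is.null(dim(uv))) uv <- matrix(as.numeric(uv), ncol = 2, byrow = TRUE)
  depth <- rep_len(as.numeric(depth), nrow(uv))
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("depth must be finite and positive (0 encodes a missing measurement)")
  cbind(
    x = (uv[, 1] - k$cx) * depth / k$fx,
    y = (uv[, 2] - k$cy) * depth / k$fy,
    z = depth)
}

#' Intrinsics after uniformly resizing the image
#'
#' Resizing an image by a factor `s` scales the pixel-represented focal
#' length and the optical centre by `s`; the physical camera is unchanged.
#' This is the transform underlying the input-resize migration correction:
#' enlarging the input raises `fx`/`fy` in pixel units, which is what a
#' depth network trained at another camera's focal length responds to.
#'
#' @param k A [camera_intrinsics] object.
#' @param s Scale factor, `> 0`.
#' @return New `camera_intrinsics` with `fx, fy, cx, cy` scaled by `s` and
#'   pixel dimensions rounded to the nearest integer.
#' @export
intrinsics_resize <- function(k, s) {
  stopifnot(inherits(k, "camera_intrinsics"))
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("resize factor s must be a single positive number")
  camera_intrinsics(
    fx = k$fx * s, fy = k$fy * s, cx = k$cx * s, cy = k$cy * s,
    width = max(1L, as.integer(round(k$width * s))),
    height = max(1L, as.integer(round(k$height * s))))
}

#' Intrinsics after a centre crop
#'
#' Cropping removes pixels but does not rescale them, so `fx` and `fy` are
#' unchanged; only the optical centre shifts by the removed border.
#'
#' @param k A [camera_intrinsics] object.
#' @param new_width,new_height Crop size in pixels, `0 <` and `<=` the
#'   current size.
#' @return New `camera_intrinsics` for the cropped image.
#' @export
intrinsics_center_crop <- function(k, new_width, new_height) {
  stopifnot(inherits(k, "camera_intrinsics"))
  new_width <- as.integer(new_width); new_height <- as.integer(new_height)
  if (new_width < 1L || new_width > k$width ||
      new_height < 1L || new_height > k$height)
    stop("crop size must be positive and no larger than the image")
  camera_intrinsics(
    fx = k$fx, fy = k$fy,
    cx = k$cx - (k$width - new_width) / 2,
    cy = k$cy - (k$height - new_height) / 2,
    width = new_width, height = new_height)
}

#' Read or write intrinsics as JSON
#'
#' The on-disk form is a flat JSON object with keys `fx`, `fy`, `cx`, `cy`,
#' `width`, `height`.
#'
#' @param k A [camera_intrinsics] object.
#' @param path File path.
#' @return `read_intrinsics()` returns a `camera_intrinsics`;
#'   `write_intrinsics()` returns `path` invisibly.
#' @export
write_intrinsics <- function(k, path) {
  stopifnot(inherits(k, "camera_intrinsics"))
  jsonlite::write_json(unclass(k), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intrinsics
#' @export
read_intrinsics <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("fx", "fy", "cx", "cy", "width", "height")
  if (!all(need %in% names(j)))
    stop("intrinsics JSON must contain keys: ", paste(need, collapse = ", "))
  do.call(camera_intrinsics, j[need])
}

to_xyz_matrix <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), ncol = 3, byrow = TRUE)
  if (ncol(xyz) != 3) stop("points must have 3 columns (X, Y, Z)")
  storage.mode(xyz) <- "double"
  xyz
}
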