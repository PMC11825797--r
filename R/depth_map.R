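#' Metric depth maps with a zero-as-missing convention
#'
#' A depth map is a per-pixel grid of distances along the camera's optical
#' axis, in metres. A value of 0 encodes a missing measurement (depth sensors
#' return null where stereo matching fails); all valid values are positive
#' and bounded by the sensor's stored range, 20 m by default.
#'
#' The grid is stored as a numeric matrix with rows = image rows (v) and
#' columns = image columns (u), matching how PNG images decode.
#'
#' @param values Numeric matrix of depths in metres; finite, `>= 0`.
#' @param max_range Largest representable depth in metres (default 20).
#'   Values above it are rejected at construction; use `Inf` for unbounded
#'   model predictions.
#' @return An object of class `depth_map` (a numeric matrix with a
#'   `max_range` attribute).
#' @export
depth_map <- function(values, max_range = 20) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("depth values must be finite (use 0 for missing)")
  if (any(values < 0))
    stop("depth values must be non-negative")
  if (is.finite(max_range) && any(values > max_range))
    stop(sprintf("depth values exceed max_range = %g m", max_range))
  structure(values, max_range = max_range, class = c("depth_map", "matrix"))
}

#' @export
print.depth_map <- function(x, ...) {
  valid <- x > 0
  cat(sprintf("depth_map: %dx%d px, %.1f%% valid, range %.3f-%.3f m (max_range %g)\n",
              ncol(x), nrow(x), 100 * mean(valid),
              if (any(valid)) min(x[valid]) else NA_real_,
              if (any(valid)) max(x[valid]) else NA_real_,
              attr(x, "max_range")))
  invisible(x)
}

#' Write a depth map as a 16-bit millimetre PNG
#'
#' Depths in metres are multiplied by 1000, rounded to the nearest
#' millimetre, and stored as unsigned 16-bit integers in a single-channel
#' PNG; 0 keeps meaning "missing". Millimetre rounding preserves three
#' decimals, so a decode reproduces every valid pixel within 0.0005 m.
#'
#' @param d A [depth_map].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(d, path) {
  stopifnot(inherits(d, "depth_map"))
  mm <- round(unclass(d) * 1000)
  mm[mm > 65535] <- 65535
  storage.mode(mm) <- "integer"
  write_png16(mm, path)
}

#' Read a 16-bit millimetre PNG as a depth map
#'
#' Stored values are interpreted as millimetres and divided by 1000. Values
#' above `max_range` are treated as missing (set to 0) rather than clipped:
#' the sensor's stated range bounds what was ever trusted, and a
#' navigation stack should not act on a fabricated 20 m reading.
#'
#' @param path PNG file path; must be single-channel 16-bit, otherwise a
#'   format error naming the offending property is raised.
#' @param max_range Depth range in metres; default 20.
#' @return A [depth_map].
#' @export
read_depth_png <- function(path, max_range = 20) {
  vals <- read_png_samples(path, require_bits = 16L)
  m <- vals / 1000
  m[m > max_range] <- 0
  depth_map(m, max_range = max_range)
}

#' Validity mask of a depth map
#'
#' A pixel is valid iff its depth is positive (not missing) and, when an
#' evaluation range is given, lies within it. Evaluation on the near field
#' only (e.g. 0-5 m for in-field navigation) is expressed through
#' `min_depth`/`max_depth`.
#'
#' @param d A [depth_map].
#' @param min_depth,max_depth Evaluation range in metres; a pixel is valid
#'   iff `depth > 0`, `depth >= min_depth` and `depth <= max_depth`.
#' @return A logical matrix of the same shape as `d`.
#' @export
depth_validity <- function(d, min_depth = 0, max_depth = attr(d, "max_range")) {
  stopifnot(inherits(d, "depth_map"))
  if (min_depth < 0 || max_depth <= 0) stop("invalid depth range")
  v <- unclass(d)
  v > 0 & v >= min_depth & v <= max_depth
}
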