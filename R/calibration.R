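#' Grid-search calibration of a migrated depth provider
#'
#' A depth model trained with one camera systematically mis-scales its
#' predictions when fed images from a camera with a different
#' pixel-represented focal length. Both corrections search an explicit grid
#' for the factor minimising a masked depth metric over a set of paired
#' (image, reference-depth) calibration samples:
#'
#' * `calibrate_output_scale()` divides the predicted depths by each
#'   candidate factor — the reference maps are never touched.
#' * `calibrate_input_resize()` feeds the provider the input resized by each
#'   candidate factor, then resamples the prediction back to the reference
#'   resolution with value-preserving nearest-neighbour mapping (never
#'   interpolating across the 0-missing sentinel) before scoring.
#'
#' The default objective is ABS-REL evaluated on the 0-5 m reference range:
#' navigation only needs near-field distances and sensor references degrade
#' with range. Scores are unweighted means over the calibration pairs.
#'
#' @param provider A function `(image, s = 1) -> depth_map`: the model
#'   under calibration. Must be deterministic for fixed input and `s`.
#' @param pairs A list of calibration samples, each a list with elements
#'   `image` (passed through to the provider; may be `NULL` for synthetic
#'   providers) and `label` (reference [depth_map]).
#' @param grid Candidate factors, all `> 0`. Defaults: 0.25-4.0 step 0.01
#'   for the output scale, 0.5-4.0 step 0.02 for the input resize.
#' @param objective Metric name to minimise: one of `"abs_rel"`, `"rmse"`,
#'   `"rmse_log"`, `"sq_rel"`, `"silog"`.
#' @param min_depth,max_depth Evaluation range on the reference depths (m).
#' @return A `calibration_result` list: `method`, `factor` (the arg-min),
#'   `objective`, `objective_value`, and `grid` (a data frame of all
#'   factors and scores).
#' @export
calibrate_output_scale <- function(provider, pairs,
                                   grid = seq(0.25, 4, by = 0.01),
                                   objective = "abs_rel",
                                   min_depth = 0, max_depth = 5) {
  check_grid(grid)
  obj <- objective_fn(objective)
  mv <- lapply(pairs, function(p) {
    pred <- provider(p$image, s = 1)
    pair_masked(pred, p$label, min_depth, max_depth)
  })
  scores <- vapply(grid, function(k) {
    mean(vapply(mv, function(v) obj(v$pred / k, v$gt), numeric(1)))
  }, numeric(1))
  calibration_result("output_scale", grid, scores, objective)
}

#' @rdname calibrate_output_scale
#' @export
calibrate_input_resize <- function(provider, pairs,
                                   grid = seq(0.5, 4, by = 0.02),
                                   objective = "abs_rel",
                                   min_depth = 0, max_depth = 5) {
  check_grid(grid)
  obj <- objective_fn(objective)
  scores <- vapply(grid, function(s) {
    per_pair <- vapply(pairs, function(p) {
      pred <- provider(p$image, s = s)
      pred_native <- resize_nearest(unclass(pred), dim(p$label)[1], dim(p$label)[2])
      v <- pair_masked(pred_native, p$label, min_depth, max_depth)
      obj(v$pred, v$gt)
    }, numeric(1))
    mean(per_pair)
  }, numeric(1))
  calibration_result("input_resize", grid, scores, objective)
}

#' Apply an output-scale correction to a depth map
#'
#' Divides every valid depth by the calibrated factor; missing pixels (0)
#' stay missing. Input-resize corrections cannot be applied after the fact —
#' they change what the model is shown — so passing one is an error.
#'
#' @param depth A [depth_map].
#' @param result A `calibration_result` with `method == "output_scale"`,
#'   or a bare positive number.
#' @return The corrected [depth_map].
#' @export
apply_depth_scale <- function(depth, result) {
  stopifnot(inherits(depth, "depth_map"))
  if (inherits(result, "calibration_result")) {
    if (result$method != "output_scale")
      stop("an input_resize calibration is applied by resizing the model's ",
           "input image at inference time, not by rescaling an existing map")
    factor <- result$factor
  } else {
    factor <- result
  }
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  d <- unclass(depth)
  d[d > 0] <- d[d > 0] / factor
  depth_map(d, max_range = attr(depth, "max_range"))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result (%s): factor %.4g, %s = %.6g over %d grid point(s)\n",
              x$method, x$factor, x$objective, x$objective_value, nrow(x$grid)))
  invisible(x)
}

#' Serialize a calibration result to JSON
#'
#' @param result A `calibration_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(method = result$method, factor = result$factor,
         objective = result$objective,
         objective_value = result$objective_value,
         grid = result$grid),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

# helpers --------------------------------------------------------------------

check_grid <- function(grid) {
  if (length(grid) < 1L || any(!is.finite(grid)) || any(grid <= 0))
    stop("calibration grid must be non-empty with all factors > 0")
}

objective_fn <- function(name) {
  switch(name,
         abs_rel = abs_rel_vec,
         rmse = rmse_vec,
         rmse_log = rmse_log_vec,
         sq_rel = sq_rel_vec,
         silog = function(p, g) silog_vec(p, g, "variance"),
         stop("unknown objective: ", name))
}

pair_masked <- function(pred, label, min_depth, max_depth) {
  pred <- unclass(as.matrix(pred)); label <- unclass(as.matrix(label))
  if (!all(dim(pred) == dim(label)))
    stop("prediction and label shapes differ")
  m <- label > 0 & label >= min_depth & label <= max_depth
  if (!any(m)) stop("objective undefined: no valid reference pixels in range")
  list(pred = pred[m], gt = label[m])
}

calibration_result <- function(method, grid, scores, objective) {
  best <- which.min(scores)
  structure(list(method = method, factor = grid[best], objective = objective,
                 objective_value = scores[best],
                 grid = data.frame(factor = grid, score = scores)),
            class = "calibration_result")
}

# Nearest-neighbour resample of a matrix to a target size, mapping pixel
# centres; value-preserving (every output value is an input value).
resize_nearest <- function(m, new_h, new_w) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(new_h) - 0.5) * h / new_h + 0.5), 1L), h)
  ci <- pmin(pmax(floor((seq_len(new_w) - 0.5) * w / new_w + 0.5), 1L), w)
  m[ri, ci, drop = FALSE]
}
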