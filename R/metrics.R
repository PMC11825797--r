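#' Pair a predicted and a reference depth map for evaluation
#'
#' Evaluation of monocular depth predictions is always masked: the reference
#' ("label") map from a depth camera is sparse, and only pixels where it is
#' non-null — and, optionally, within an evaluation range — enter any metric.
#'
#' @param pred Predicted [depth_map] (or plain numeric matrix).
#' @param label Reference [depth_map] from the depth sensor.
#' @param mask Optional logical matrix overriding the derived mask.
#' @param min_depth,max_depth Evaluation range applied to the label (metres);
#'   defaults keep every non-null label pixel.
#' @return An object of class `depth_pair` with elements `pred`, `label`,
#'   `mask` and `n` (count of valid pixels, which must be at least 1).
#' @export
depth_pair <- function(pred, label, mask = NULL, min_depth = 0, max_depth = Inf) {
  pred <- as.matrix(pred); label <- as.matrix(label)
  if (!all(dim(pred) == dim(label)))
    stop("pred and label shapes differ")
  if (is.null(mask)) {
    mask <- label > 0 & label >= min_depth & label <= max_depth
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(label))) stop("mask shape differs from maps")
    mask <- mask & label > 0
  }
  n <- sum(mask)
  if (n < 1L) stop("no valid label pixels under the mask/range")
  structure(list(pred = unclass(pred), label = unclass(label),
                 mask = mask, n = n),
            class = "depth_pair")
}

masked_vectors <- function(pair) {
  stopifnot(inherits(pair, "depth_pair"))
  list(pred = pair$pred[pair$mask], gt = pair$label[pair$mask])
}

require_positive_pred <- function(pred) {
  bad <- sum(!(pred > 0))
  if (bad > 0)
    stop(sprintf("log-based metric undefined: %d masked prediction(s) are not positive", bad))
}

# kernels on masked vectors -------------------------------------------------

abs_rel_vec <- function(pred, gt) 100 * mean(abs(pred - gt) / gt)
rmse_vec <- function(pred, gt) sqrt(mean((pred - gt)^2))
sq_rel_vec <- function(pred, gt) mean(((pred - gt) / gt)^2)
rmse_log_vec <- function(pred, gt) {
  require_positive_pred(pred)
  sqrt(mean((log(pred) - log(gt))^2))
}
delta_vec <- function(pred, gt, n) {
  require_positive_pred(pred)
  100 * mean(pmax(gt / pred, pred / gt) < 1.25^n)
}
silog_vec <- function(pred, gt, form = c("variance", "printed")) {
  form <- match.arg(form)
  require_positive_pred(pred)
  d <- log(pred) - log(gt)
  if (form == "variance") mean(d^2) - mean(d)^2 else mean(d^2) + mean(d)^2
}

# public pair-based metrics --------------------------------------------------

#' Masked depth-evaluation metrics
#'
#' The standard accuracy metrics of monocular depth estimation, each averaged
#' over the valid (masked) label pixels of a [depth_pair]:
#'
#' * `abs_rel()`: mean absolute relative error,
#'   \eqn{\frac{100}{N}\sum |y_{pred}-y_{gt}|/y_{gt}} (percent).
#' * `rmse()`: root mean squared error (metres).
#' * `rmse_log()`: RMSE of natural-log depths (dimensionless).
#' * `sq_rel()`: mean squared relative error
#'   \eqn{\frac{1}{N}\sum ((y_{pred}-y_{gt})/y_{gt})^2} (dimensionless).
#' * `delta_accuracy()`: percentage of pixels whose ratio
#'   \eqn{\max(y_{gt}/y_{pred},\, y_{pred}/y_{gt})} is strictly below
#'   \eqn{1.25^n}, the threshold accuracies \eqn{\delta_1,\delta_2,\delta_3}.
#'
#' Log and ratio metrics require every masked prediction to be positive; a
#' violation is an error (silently dropping such pixels would bias model
#' comparisons).
#'
#' @param pair A [depth_pair].
#' @param n Threshold exponent for `delta_accuracy()`: 1, 2 or 3.
#' @return A single number; percentages are on the 0-100 scale.
#' @export
abs_rel <- function(pair) { v <- masked_vectors(pair); abs_rel_vec(v$pred, v$gt) }

#' @rdname abs_rel
#' @export
rmse <- function(pair) { v <- masked_vectors(pair); rmse_vec(v$pred, v$gt) }

#' @rdname abs_rel
#' @export
rmse_log <- function(pair) { v <- masked_vectors(pair); rmse_log_vec(v$pred, v$gt) }

#' @rdname abs_rel
#' @export
sq_rel <- function(pair) { v <- masked_vectors(pair); sq_rel_vec(v$pred, v$gt) }

#' @rdname abs_rel
#' @export
delta_accuracy <- function(pair, n) {
  stopifnot(n %in% 1:3)
  v <- masked_vectors(pair)
  delta_vec(v$pred, v$gt, n)
}

#' Scale-invariant log error (silog)
#'
#' With \eqn{d_i = \log y_{pred,i} - \log y_{gt,i}} over the masked pixels,
#' the default `"variance"` form is
#' \eqn{\frac{1}{N}\sum d_i^2 - (\frac{1}{N}\sum d_i)^2}, the variance of the
#' log-ratio. It is exactly 0 whenever the prediction is a constant multiple
#' of the reference — the scale-invariance the metric is named for. The
#' `"printed"` form adds the squared-mean term instead of subtracting it;
#' it appears in some typeset formulations but is not scale-invariant, and is
#' provided for comparison only.
#'
#' @param pair A [depth_pair].
#' @param form `"variance"` (default) or `"printed"`.
#' @return A non-negative scalar.
#' @export
silog <- function(pair, form = c("variance", "printed")) {
  v <- masked_vectors(pair)
  silog_vec(v$pred, v$gt, form)
}

#' Scale-invariant log training loss
#'
#' The masked training loss used to fit depth networks on sparse labels:
#' \eqn{\alpha \sqrt{\frac{1}{N}\sum d_i^2 - \lambda (\frac{1}{N}\sum d_i)^2}}
#' with \eqn{d_i} as in [silog()]. Masked-out pixels (null labels) never
#' contribute. With `lambda = 1` this is `alpha` times the standard deviation
#' of `d`; `lambda < 1` re-introduces some absolute-scale sensitivity.
#'
#' @param pair A [depth_pair].
#' @param lambda Variance weight in `[0, 1]`, default 0.85.
#' @param alpha Output scale, default 10.
#' @return A non-negative scalar. A negative radicand (possible only through
#'   floating-point rounding when `lambda >= 1`) is clamped to 0 with a
#'   warning.
#' @export
silog_loss <- function(pair, lambda = 0.85, alpha = 10) {
  v <- masked_vectors(pair)
  require_positive_pred(v$pred)
  d <- log(v$pred) - log(v$gt)
  rad <- mean(d^2) - lambda * mean(d)^2
  if (rad < 0) {
    warning("silog radicand below 0 (", rad, "); clamped to 0")
    rad <- 0
  }
  alpha * sqrt(rad)
}

#' Chamfer distance between two point clouds
#'
#' Symmetric nearest-neighbour distance between point sets:
#' \deqn{CD(A, B) = \frac{1}{|A|}\sum_{a} \min_b \|a-b\|^2
#'               + \frac{1}{|B|}\sum_{b} \min_a \|a-b\|^2}
#' under the default squared convention (`squared = FALSE` uses Euclidean
#' distances instead). Zero iff the two sets are equal as sets; symmetric;
#' used here to compare predicted and reference navigation points or row
#' point clouds.
#'
#' @param a,b Non-empty `n x d` numeric matrices of points (rows = points).
#' @param squared Use squared distances (default) or plain Euclidean.
#' @return A non-negative scalar.
#' @export
chamfer_distance <- function(a, b, squared = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  storage.mode(a) <- "double"; storage.mode(b) <- "double"
  if (nrow(a) < 1L || nrow(b) < 1L)
    stop("chamfer distance requires two non-empty point clouds ",
         "(an empty cloud means upstream filtering removed every point)")
  dab <- .nn_sqdist(a, b)
  dba <- .nn_sqdist(b, a)
  if (!squared) {
    dab <- sqrt(dab); dba <- sqrt(dba)
  }
  mean(dab) + mean(dba)
}

#' Evaluate all eight depth metrics on one pair
#'
#' Computes ABS-REL, RMSE, silog, the three threshold accuracies, RMSE of
#' log depths and the squared relative error on the identical mask, in the
#' conventional reporting order.
#'
#' @param pair A [depth_pair].
#' @param silog_form Passed to [silog()].
#' @return A `metric_report`: a named list with elements `abs_rel` (%),
#'   `rmse` (m), `silog`, `delta1`, `delta2`, `delta3` (%), `rmse_log`,
#'   `sq_rel`, and attribute `n` (pixel count).
#' @export
evaluate_depth <- function(pair, silog_form = "variance") {
  v <- masked_vectors(pair)
  structure(
    list(abs_rel = abs_rel_vec(v$pred, v$gt),
         rmse = rmse_vec(v$pred, v$gt),
         silog = silog_vec(v$pred, v$gt, silog_form),
         delta1 = delta_vec(v$pred, v$gt, 1),
         delta2 = delta_vec(v$pred, v$gt, 2),
         delta3 = delta_vec(v$pred, v$gt, 3),
         rmse_log = rmse_log_vec(v$pred, v$gt),
         sq_rel = sq_rel_vec(v$pred, v$gt)),
    n = pair$n, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("ABS-REL%  RMSE(m)   Silog  delta1%  delta2%  delta3%  RMSElog  SQ-REL\n")
  cat(sprintf("%8.2f %8.3f %7.4f %8.2f %8.2f %8.2f %8.4f %7.4f\n",
              x$abs_rel, x$rmse, x$silog, x$delta1, x$delta2, x$delta3,
              x$rmse_log, x$sq_rel))
  invisible(x)
}

#' Average metric reports across images
#'
#' Dataset-level scores are the unweighted mean of the per-image metrics
#' (not a pooled-pixel computation), so every image counts equally
#' regardless of how many valid label pixels it has.
#'
#' @param reports A list of `metric_report` objects.
#' @return A `metric_report` of the element-wise means, with attribute `n`
#'   equal to the number of images.
#' @export
mean_report <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "metric_report")))
  keys <- names(reports[[1]])
  out <- lapply(keys, function(k)
    mean(vapply(reports, function(r) r[[k]], numeric(1))))
  names(out) <- keys
  structure(out, n = length(reports), class = "metric_report")
}

#' Serialize a metric report to JSON
#'
#' @param report A `metric_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
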