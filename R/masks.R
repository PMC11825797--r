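#' Instance masks of crop-row instances
#'
#' An integer label image: 0 is background, each positive integer labels the
#' pixels of one row instance (one rolled stubble row in the field scene).
#'
#' @param labels Integer matrix (rows = image rows); values `>= 0`.
#' @return An object of class `instance_masks`.
#' @export
instance_masks <- function(labels) {
  labels <- as.matrix(labels)
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers (0 = background)")
  storage.mode(labels) <- "integer"
  structure(labels, class = c("instance_masks", "matrix"))
}

#' @export
print.instance_masks <- function(x, ...) {
  ids <- instance_ids(x)
  cat(sprintf("instance_masks: %dx%d px, %d instance(s)%s\n",
              ncol(x), nrow(x), length(ids),
              if (length(ids)) paste0(" [", paste(ids, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Distinct instance ids present in a mask set
#'
#' @param masks An [instance_masks] object.
#' @return Sorted integer vector of the nonzero labels present.
#' @export
instance_ids <- function(masks) {
  stopifnot(inherits(masks, "instance_masks"))
  ids <- sort(unique(as.vector(masks)))
  ids[ids > 0L]
}

#' Read or write instance masks as label PNGs
#'
#' Masks are stored as single-channel PNGs whose sample values are the
#' instance ids (0 = background). Files are written 16-bit; both 8-bit and
#' 16-bit label images are accepted on read.
#'
#' @param masks An [instance_masks] object.
#' @param path File path.
#' @return `read_mask_png()` returns an `instance_masks`;
#'   `write_mask_png()` returns `path` invisibly.
#' @export
write_mask_png <- function(masks, path) {
  stopifnot(inherits(masks, "instance_masks"))
  write_png16(unclass(masks), path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  instance_masks(read_png_samples(path))
}
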