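# Minimal 16-bit grayscale PNG writer.
#
# Depth maps follow the millimetre-in-uint16 convention, which needs 16-bit
# single-channel PNG output; png::writePNG emits 8 bits per channel only, so
# the few required chunks (IHDR / IDAT / IEND) are assembled here. Reading
# goes through png::readPNG, which decodes 16-bit losslessly. memCompress()
# produces an RFC-1950 zlib stream, exactly what IDAT carries; chunk CRCs are
# computed in C.

png16_u32 <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, x %/% 2^16, x %/% 2^8, x) %% 256)
}

png16_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(png16_u32(length(data)), td, png16_u32(.crc32(td)))
}

# vals: integer matrix (rows = image rows), values in [0, 65535]
write_png16 <- function(vals, path) {
  h <- nrow(vals); w <- ncol(vals)
  stopifnot(h >= 1L, w >= 1L)
  if (any(vals < 0L | vals > 65535L))
    stop("16-bit PNG sample values must lie in [0, 65535]")
  # scanlines: filter byte 0, then big-endian 16-bit samples
  sc <- matrix(0L, nrow = 1L + 2L * w, ncol = h)
  idx <- seq_len(w) * 2L
  sc[idx, ] <- t(vals %/% 256L)
  sc[idx + 1L, ] <- t(vals %% 256L)
  ihdr <- c(png16_u32(w), png16_u32(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # bit depth 16, grayscale
  out <- c(as.raw(c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)),
           png16_chunk("IHDR", ihdr),
           png16_chunk("IDAT", memCompress(as.raw(sc), "gzip")),
           png16_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

# Read a PNG as an integer sample matrix, checking channel count/bit depth.
# Returns the matrix with attributes bit_depth.
read_png_samples <- function(path, require_bits = NULL) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (length(dim(img)) == 3L)
    stop(sprintf("expected a single-channel PNG, got %d channels: %s",
                 dim(img)[3], path))
  bits <- info$bit.depth
  if (!is.null(require_bits) && bits != require_bits)
    stop(sprintf("expected a %d-bit PNG, got bit depth %d: %s",
                 require_bits, bits, path))
  vals <- round(img * (2^bits - 1))
  attributes(vals) <- list(dim = dim(img))
  storage.mode(vals) <- "integer"
  vals
}
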