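# Minimal PNG codec (grayscale 8/16-bit and 8-bit RGB, no interlacing).
#
# The slice exporter needs bit-exact lossless PNG round trips; no PNG
# library is guaranteed in the target R installation, so the codec is
# self-contained.  memCompress(type = "gzip") emits an RFC-1950 zlib
# stream, which is exactly what an IDAT chunk holds.

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_to_raw_be(length(data)), body, u32_to_raw_be(crc32(body)))
}

#' Write a grayscale PNG from an integer matrix
#'
#' Rows of the matrix become scanlines.  Values must already lie in
#' `[0, 2^bit_depth - 1]`; storage is bit-exact (filter type 0, zlib).
#'
#' @param m integer-valued matrix.
#' @param path output file path.
#' @param bit_depth 8 or 16.
#' @export
png_write_gray <- function(m, path, bit_depth = 8) {
  if (any(!is.finite(m))) stopf("png_write_gray: non-finite pixel values")
  maxval <- 2^bit_depth - 1
  if (any(m < 0) || any(m > maxval)) stopf("png_write_gray: pixel values outside [0, %d]", maxval)
  h <- nrow(m); w <- ncol(m)
  mi <- round(m)
  if (bit_depth == 8) {
    sc <- rbind(0, t(mi))                      # (w+1) x h, column = one scanline
  } else if (bit_depth == 16) {
    tm <- t(mi)                                # w x h
    hi <- tm %/% 256; lo <- tm %% 256
    sc <- matrix(0, 2 * w + 1, h)
    sc[seq(2, 2 * w, by = 2), ] <- hi
    sc[seq(3, 2 * w + 1, by = 2), ] <- lo
  } else stopf("png_write_gray: bit_depth must be 8 or 16")
  raw_data <- as.raw(as.vector(sc))
  ihdr <- c(u32_to_raw_be(w), u32_to_raw_be(h),
            as.raw(c(bit_depth, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(raw_data, "gzip")),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

#' Write an 8-bit RGB PNG from a h x w x 3 integer array
#' @param a array with values in `[0, 255]`.
#' @param path output file path.
#' @export
png_write_rgb <- function(a, path) {
  stopifnot(length(dim(a)) == 3, dim(a)[3] == 3)
  if (any(!is.finite(a)) || any(a < 0) || any(a > 255)) {
    stopf("png_write_rgb: pixel values must be finite and in [0, 255]")
  }
  h <- dim(a)[1]; w <- dim(a)[2]
  sc <- matrix(0, 3 * w + 1, h)
  for (ch in 1:3) sc[seq(1 + ch, 3 * w + 1, by = 3), ] <- t(round(a[, , ch]))
  ihdr <- c(u32_to_raw_be(w), u32_to_raw_be(h), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(as.raw(as.vector(sc)), "gzip")),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

paeth_predictor <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' Read a grayscale PNG into an integer matrix
#'
#' Supports non-interlaced grayscale images at bit depth 8 or 16 with any
#' scanline filter (types 0-4).  Returns the stored integers exactly.
#'
#' @param path PNG file path.
#' @return integer matrix (rows = scanlines).
#' @export
png_read_gray <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 8 ||
      !identical(as.integer(bytes[1:8]), c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L))) {
    stopf("not a PNG file: %s", path)
  }
  pos <- 9L
  idat <- raw()
  ihdr <- NULL
  while (pos + 8 <= length(bytes) + 1) {
    len <- raw_be_to_u32(bytes[pos:(pos + 3)])
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    data <- if (len > 0) bytes[(pos + 8):(pos + 7 + len)] else raw()
    if (type == "IHDR") ihdr <- data
    if (type == "IDAT") idat <- c(idat, data)
    if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(ihdr)) stopf("PNG missing IHDR: %s", path)
  w <- raw_be_to_u32(ihdr[1:4]); h <- raw_be_to_u32(ihdr[5:8])
  bit_depth <- as.integer(ihdr[9]); color_type <- as.integer(ihdr[10])
  if (color_type != 0L) stopf("png_read_gray: only grayscale PNGs supported (color type %d)", color_type)
  if (!bit_depth %in% c(8L, 16L)) stopf("png_read_gray: unsupported bit depth %d", bit_depth)
  if (as.integer(ihdr[13]) != 0L) stopf("png_read_gray: interlaced PNG unsupported")
  bpp <- bit_depth %/% 8L
  stride <- w * bpp
  raw_sc <- memDecompress(idat, "gzip")
  out <- matrix(0L, h, w)
  prev <- integer(stride)
  sc <- matrix(as.integer(raw_sc), stride + 1L, h)
  for (y in seq_len(h)) {
    filt <- sc[1L, y]
    line <- sc[-1L, y]
    if (filt == 1L) {                      # Sub
      for (i in seq_len(stride)) {
        a <- if (i > bpp) line[i - bpp] else 0L
        line[i] <- (line[i] + a) %% 256L
      }
    } else if (filt == 2L) {               # Up
      line <- (line + prev) %% 256L
    } else if (filt == 3L) {               # Average
      for (i in seq_len(stride)) {
        a <- if (i > bpp) line[i - bpp] else 0L
        line[i] <- (line[i] + (a + prev[i]) %/% 2L) %% 256L
      }
    } else if (filt == 4L) {               # Paeth
      for (i in seq_len(stride)) {
        a <- if (i > bpp) line[i - bpp] else 0L
        cc <- if (i > bpp) prev[i - bpp] else 0L
        line[i] <- (line[i] + paeth_predictor(a, prev[i], cc)) %% 256L
      }
    } else if (filt != 0L) stopf("png_read_gray: unknown filter type %d", filt)
    prev <- line
    out[y, ] <- if (bpp == 1L) line else line[seq(1, stride, 2)] * 256L + line[seq(2, stride, 2)]
  }
  out
}
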