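#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero ("half-up" for nonnegative input)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# CRC-32 (ISO 3309), table-driven, over a raw vector.  R's bitwShiftR is a
# logical (zero-fill) shift on the 32-bit pattern, so the signed integer
# representation carries the unsigned bit pattern throughout.
.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit pattern
  tab <- integer(256L)
  for (n in 0L:255L) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  .crc_env$tab <- tab
  tab
}

#' CRC-32 checksum of a raw vector, returned as a double in [0, 2^32)
#' @noRd
crc32 <- function(bytes, init = 0) {
  tab <- crc32_table()
  c <- bitwXor(unsigned_to_int(init), -1L)
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    c <- bitwXor(bitwShiftR(c, 8L), tab[bitwAnd(bitwXor(c, b[i]), 255L) + 1L])
  }
  int_to_unsigned(bitwXor(c, -1L))
}

int_to_unsigned <- function(x) {
  x <- as.numeric(x)
  ifelse(x < 0, x + 4294967296, x)
}

unsigned_to_int <- function(x) {
  x <- as.numeric(x)
  as.integer(ifelse(x >= 2147483648, x - 4294967296, x))
}

u32_to_raw_be <- function(n) {
  n <- as.numeric(n)
  as.raw(c(n %/% 16777216 %% 256, n %/% 65536 %% 256, n %/% 256 %% 256, n %% 256))
}

raw_be_to_u32 <- function(r) {
  v <- as.numeric(as.integer(r))
  v[1] * 16777216 + v[2] * 65536 + v[3] * 256 + v[4]
}

#' Bilinear resize of a numeric matrix
#'
#' Resamples a 2D intensity grid to a new height and width by bilinear
#' interpolation, treating pixel centers as sample points (align-corners
#' convention when both dimensions exceed 1).  Used to fit raw slice
#' geometry (45x54 fMRI, 91x109 structural) to the transformer input sizes
#' (56x56, 112x112, 224x224).
#'
#' @param m numeric matrix.
#' @param out_h,out_w output dimensions in pixels.
#' @return numeric `out_h` x `out_w` matrix.
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  if (!is.matrix(m)) m <- as.matrix(m)
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  ry <- if (out_h > 1) (h - 1) / (out_h - 1) else 0
  rx <- if (out_w > 1) (w - 1) / (out_w - 1) else 0
  y <- (seq_len(out_h) - 1) * ry
  x <- (seq_len(out_w) - 1) * rx
  y0 <- pmin(floor(y), h - 1); x0 <- pmin(floor(x), w - 1)
  y1 <- pmin(y0 + 1, h - 1);   x1 <- pmin(x0 + 1, w - 1)
  fy <- y - y0; fx <- x - x0
  m00 <- m[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
  m10 <- m[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
  m01 <- m[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
  m11 <- m[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
  fym <- rep(fy, out_w); fxm <- rep(fx, each = out_h)
  out <- (1 - fym) * (1 - fxm) * m00 + fym * (1 - fxm) * m10 +
    (1 - fym) * fxm * m01 + fym * fxm * m11
  matrix(out, out_h, out_w)
}

# Deterministic 31-bit stream seed derived from a base seed and a string key,
# so each subject owns an independent reproducible random stream.
derive_seed <- function(seed, key) {
  h <- crc32(charToRaw(as.character(key)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
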