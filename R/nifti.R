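# Minimal NIfTI-1 volume I/O (.nii / .nii.gz, single file).
#
# The cohort generator emits float32 volumes in the exact geometry the
# pipeline consumes (45x54x45xT rs-fMRI, 91x109x91 structural grey-matter
# maps); the reader accepts the common scalar datatypes and applies the
# scl_slope/scl_inter scaling.  Axes follow the NIfTI convention: x is the
# fastest-varying index, matching R's column-major array layout.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double", size = 4, signed = TRUE),
                 `64` = list(what = "double", size = 8, signed = TRUE))

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' Data are stored as little-endian float32 with an identity sform.
#'
#' @param vol numeric 3D or 4D array.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param pixdim voxel sizes (mm) and, for 4D data, the repetition time in
#'   seconds; recycled/padded to the array rank.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, pixdim = NULL) {
  nd <- length(dim(vol))
  if (!nd %in% c(3L, 4L)) stopf("write_nifti: array must be 3D or 4D, got %dD", nd)
  if (any(!is.finite(vol))) stopf("write_nifti: non-finite voxel values")
  dims <- dim(vol)
  pixdim <- rep_len(pixdim %||% 1, nd)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wr <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                                   # sizeof_hdr
  wr(34); writeBin(charToRaw("r"), con); wr(1)  # data_type..regular, dim_info
  wi(c(nd, dims, rep(1L, 7 - nd)), 2)           # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1..3, intent_code
  wi(16L, 2); wi(32L, 2); wi(0L, 2)             # datatype float32, bitpix, slice_start
  wf(c(1, pixdim, rep(1, 7 - nd)))              # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wr(1); writeBin(as.raw(10L), con)  # slice_end, slice_code, xyzt_units (mm|sec)
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)           # cal_max/min, slice_duration, toffset, glmax/min
  wr(80 + 24)                                   # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code 0, sform_code 1
  wf(rep(0, 6))                                 # quatern b,c,d, qoffset x,y,z
  wf(c(pixdim[1], 0, 0, 0,  0, pixdim[2], 0, 0,  0, 0, pixdim[3], 0))  # srow
  wr(16)                                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  wr(4)                                         # extension flag
  writeBin(as.numeric(vol), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return numeric array (3D or 4D) with attributes `pixdim` and `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("read_nifti: no such file: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stopf("read_nifti: truncated header in %s", path)
  endian <- "little"
  ri <- function(off, size, n = 1) readBin(hdr[(off + 1):(off + size * n)], "integer",
                                           n = n, size = size, endian = endian)
  rf <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                     n = n, size = 4, endian = endian)
  if (ri(0, 4) != 348L) {
    endian <- "big"
    if (ri(0, 4) != 348L) stopf("read_nifti: %s is not a NIfTI-1 file", path)
  }
  dim8 <- ri(40, 2, 8)
  nd <- dim8[1]
  if (!nd %in% 1:7) stopf("read_nifti: bad dimension count %d", nd)
  dims <- dim8[2:(1 + nd)]
  datatype <- ri(70, 2)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stopf("read_nifti: unsupported datatype code %d", datatype)
  pixdim <- rf(76, 8)[2:(1 + nd)]
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  data <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed, endian = endian)
  if (length(data) < n) stopf("read_nifti: truncated data in %s", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  arr <- array(as.numeric(data), dim = dims)
  attr(arr, "pixdim") <- pixdim
  attr(arr, "datatype") <- datatype
  arr
}
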