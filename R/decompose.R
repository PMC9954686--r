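# Volume-to-slice decomposition.
#
# A 4D time course (or 3D map, treated as T = 1) is cut along the axial
# (z) and time (t) axes into 2D images.  The last `drop_tail` axial slices
# are discarded, and a slice is exported only if its raw voxel intensity
# sum is nonzero; surviving slices are stored as lossless PNGs with a
# per-volume linear intensity window.

#' Decomposition parameters
#'
#' @param drop_tail number of highest-z axial slices to discard (default 10).
#' @param bit_depth PNG bit depth, 8 or 16.
#' @param scaling intensity windowing scheme; `"per_volume"` maps the raw
#'   volume's min-max range linearly onto the integer pixel range.
#' @return object of class `decompose_params`.
#' @export
decompose_params <- function(drop_tail = 10L, bit_depth = 8L, scaling = "per_volume") {
  if (drop_tail < 0) stopf("decompose_params: drop_tail must be >= 0")
  if (!bit_depth %in% c(8L, 16L)) stopf("decompose_params: bit_depth must be 8 or 16")
  if (!identical(scaling, "per_volume")) stopf("decompose_params: unknown scaling scheme")
  structure(list(drop_tail = as.integer(drop_tail), bit_depth = as.integer(bit_depth),
                 scaling = scaling), class = "decompose_params")
}

#' Quantize and write one slice as a grayscale PNG
#'
#' Pixels are mapped linearly from `window` onto `[0, 2^bit_depth - 1]`,
#' rounded half-up and clamped; PNG storage is bit-exact thereafter.  A
#' collapsed window (`min == max`) produces an all-zero image.
#'
#' @param slice_pixels numeric matrix of raw intensities.
#' @param path output PNG path.
#' @param window numeric `(min, max)` intensity window.
#' @param bit_depth 8 or 16.
#' @export
write_slice_png <- function(slice_pixels, path, window, bit_depth = 8L) {
  if (any(is.na(slice_pixels))) stopf("write_slice_png: NaN/NA pixels in %s", path)
  if (window[1] > window[2]) stopf("write_slice_png: window min > max")
  maxval <- 2^bit_depth - 1
  if (window[1] == window[2]) {
    q <- matrix(0L, nrow(slice_pixels), ncol(slice_pixels))
  } else {
    q <- round_half_up((slice_pixels - window[1]) / (window[2] - window[1]) * maxval)
    q <- pmin(pmax(q, 0), maxval)
  }
  png_write_gray(q, path, bit_depth)
}

#' Read back a slice PNG as stored integers
#' @param path PNG path.
#' @return integer matrix.
#' @export
read_slice_png <- function(path) {
  if (!file.exists(path)) stopf("read_slice_png: no such file: %s", path)
  png_read_gray(path)
}

#' Encode / parse slice file names
#'
#' File names carry the subject ID and 0-based (z, t) indices and parse
#' back losslessly: `<subject>_z<zz>_t<ttt>.png`.
#'
#' @param subject_id subject identifier (must not contain `_z` followed by digits).
#' @param z,t 0-based slice and time indices.
#' @export
slice_filename <- function(subject_id, z, t) {
  sprintf("%s_z%03d_t%04d.png", subject_id, z, t)
}

#' @rdname slice_filename
#' @param filename a name produced by [slice_filename()].
#' @return list with `subject_id`, `z`, `t`.
#' @export
parse_slice_filename <- function(filename) {
  base <- sub("\\.png$", "", basename(filename))
  m <- regmatches(base, regexec("^(.*)_z([0-9]{3})_t([0-9]{4})$", base))[[1]]
  if (length(m) != 4) stopf("parse_slice_filename: unparseable name %s", filename)
  list(subject_id = m[2], z = as.integer(m[3]), t = as.integer(m[4]))
}

#' Decompose one subject volume into 2D slice records
#'
#' Iterates z from 0 to `Z - drop_tail - 1` and t over the full time axis,
#' exporting the (x, y) plane whenever its raw voxel sum is nonzero.
#' Records are returned in (z, t) lexicographic order.
#'
#' @param volume a `subject_volume` (from [generate_cohort()] /
#'   [read_cohort()]).
#' @param params a [decompose_params()].
#' @param out_dir directory for PNG files; with `write = FALSE` no files
#'   are produced and `path` holds the would-be file names.
#' @param write write PNG files (default `TRUE` when `out_dir` is given).
#' @return data.frame with columns subject_id, label, z, t, path,
#'   sum_intensity.
#' @export
decompose_volume <- function(volume, params = decompose_params(), out_dir = NULL,
                             write = !is.null(out_dir)) {
  vox <- volume$voxels
  if (length(dim(vox)) == 3) dim(vox) <- c(dim(vox), 1L)
  dims <- dim(vox)
  Z <- dims[3]; Tn <- dims[4]
  if (params$drop_tail >= Z) stopf("decompose_volume: drop_tail (%d) >= Z (%d)", params$drop_tail, Z)
  if (write) {
    if (is.null(out_dir)) stopf("decompose_volume: out_dir required when write = TRUE")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(out_dir, 2) != 0) stopf("decompose_volume: output directory not writable: %s", out_dir)
  }
  window <- range(vox)
  z_keep <- Z - params$drop_tail
  # slice intensity sums over the raw voxels, all (z, t) at once
  sums <- matrix(colSums(matrix(vox, dims[1] * dims[2])), Z, Tn)
  recs <- list()
  for (z in seq_len(z_keep) - 1L) {
    for (t in seq_len(Tn) - 1L) {
      si <- sums[z + 1L, t + 1L]
      if (si == 0) next
      fname <- slice_filename(volume$subject_id, z, t)
      path <- if (is.null(out_dir)) fname else file.path(out_dir, fname)
      if (write) {
        write_slice_png(vox[, , z + 1L, t + 1L], path, window, params$bit_depth)
      }
      recs[[length(recs) + 1L]] <- data.frame(
        subject_id = volume$subject_id, label = volume$label,
        z = z, t = t, path = path, sum_intensity = si,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) {
    return(data.frame(subject_id = character(), label = character(),
                      z = integer(), t = integer(), path = character(),
                      sum_intensity = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

#' Decompose every subject of a cohort
#'
#' @param cohort list of `subject_volume`s.
#' @param params a [decompose_params()].
#' @param out_dir slice output directory.
#' @param write write PNG files.
#' @return combined slice record data.frame.
#' @export
decompose_cohort <- function(cohort, params = decompose_params(), out_dir = NULL,
                             write = !is.null(out_dir)) {
  do.call(rbind, lapply(cohort, decompose_volume, params = params,
                        out_dir = out_dir, write = write))
}

#' Build a training manifest from slice records and a split assignment
#'
#' @param records slice record data.frame from [decompose_volume()].
#' @param split_assignment data.frame with columns `subject_id` and `split`
#'   (a [stratified_split()] result works directly), or a named character
#'   vector mapping subject IDs to splits.
#' @return data.frame with columns path, subject_id, label, split, z, t
#'   (one row per slice, grouped by subject).
#' @export
build_manifest <- function(records, split_assignment) {
  if (is.character(split_assignment)) {
    split_assignment <- data.frame(subject_id = names(split_assignment),
                                   split = unname(split_assignment),
                                   stringsAsFactors = FALSE)
  }
  if (nrow(records) == 0) {
    return(data.frame(path = character(), subject_id = character(),
                      label = character(), split = character(),
                      z = integer(), t = integer(), stringsAsFactors = FALSE))
  }
  missing <- setdiff(unique(records$subject_id), split_assignment$subject_id)
  if (length(missing) > 0) {
    stopf("build_manifest: subjects missing from split assignment: %s",
          paste(missing, collapse = ", "))
  }
  idx <- match(records$subject_id, split_assignment$subject_id)
  out <- data.frame(path = records$path, subject_id = records$subject_id,
                    label = records$label, split = split_assignment$split[idx],
                    z = records$z, t = records$t, stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$z, out$t), ]
  rownames(out) <- NULL
  out
}
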