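# Synthetic neuroimaging cohorts.
#
# The generator emits volumes in the exact geometry of preprocessed study
# data: 4D resting-state fMRI time courses of 45 x 54 x 45 x T voxels
# (T variable per subject, modal value 140) and 3D structural grey-matter
# maps of 91 x 109 x 91 voxels.  Each subject is a brain-shaped ellipsoid
# baseline plus class-specific smooth intensity foci plus white Gaussian
# noise; a configurable fraction of axial slices is zeroed to exercise the
# empty-slice filter of the decomposition stage.

FMRI_SHAPE <- c(45L, 54L, 45L)
SMRI_SHAPE <- c(91L, 109L, 91L)
CLASS_LABELS <- c("AD", "HC", "MCI")

# Class-signal focus centers: three per class at fixed angles on a common
# in-plane ellipse ring (45% of the mask semi-axes).  A shared ring radius
# means the baseline dome has the same height at every focus, so slice
# brightness does not confound class membership; the 40-degree spacing
# keeps foci of different classes >2 in-plane sigmas apart.  Foci run the
# full z extent of the mask so every exported axial slice is informative.
CLASS_FOCI_ANGLES <- list(AD = c(0, 120, 240), HC = c(40, 160, 280),
                          MCI = c(80, 200, 320))
FOCUS_RING_RADIUS <- 0.45
FOCUS_SIGMA_FRAC <- 0.055   # in-plane Gaussian sd, fraction of min(X, Y)

#' Specify a synthetic cohort
#'
#' @param n_per_class named integer vector over `AD`, `HC`, `MCI`.
#' @param modality `"fmri"` (4D, 45x54x45xT) or `"smri"` (3D, 91x109x91).
#' @param fmri_T_range inclusive integer range the per-subject time-course
#'   length is drawn from.
#' @param fmri_T_mode modal time-course length; drawn with probability
#'   `fmri_T_mode_prob`, otherwise T is uniform on `fmri_T_range`.
#' @param fmri_T_mode_prob probability mass placed on the modal T.
#' @param effect_size amplitude of the class-specific foci at their centers,
#'   in baseline intensity units (baseline peak is 100).
#' @param noise_sd standard deviation of the additive Gaussian voxel noise.
#' @param empty_slice_prob probability that a given axial slice is zeroed
#'   across all time points.
#' @param focus_z_range fraction interval of the z axis over which the
#'   class foci are present (default the full axis).  A partial range,
#'   e.g. `c(0.25, 1)`, leaves the remaining axial slices without class
#'   information, emulating disease signatures visible only on part of
#'   the slice stack: slice-level accuracy is then capped while
#'   subject-level majority voting can still recover every subject.
#' @param seed integer master seed; per-subject streams are derived from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(AD = 3, HC = 3, MCI = 3),
                        modality = c("fmri", "smri"),
                        fmri_T_range = c(124L, 200L),
                        fmri_T_mode = 140L,
                        fmri_T_mode_prob = 0.3,
                        effect_size = 3,
                        noise_sd = 1,
                        empty_slice_prob = 0.05,
                        focus_z_range = c(0, 1),
                        seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(names(n_per_class))) names(n_per_class) <- CLASS_LABELS[seq_along(n_per_class)]
  if (!all(names(n_per_class) %in% CLASS_LABELS)) {
    stopf("cohort_spec: class labels must be among %s", paste(CLASS_LABELS, collapse = ", "))
  }
  if (any(n_per_class < 0)) stopf("cohort_spec: subject counts must be nonnegative")
  if (sum(n_per_class) == 0) stopf("cohort_spec: zero subjects requested for every class")
  if (effect_size < 0) stopf("cohort_spec: effect_size must be >= 0")
  if (noise_sd <= 0) stopf("cohort_spec: noise_sd must be > 0")
  if (empty_slice_prob < 0 || empty_slice_prob > 1) stopf("cohort_spec: empty_slice_prob must be in [0, 1]")
  if (length(focus_z_range) != 2 || focus_z_range[1] < 0 || focus_z_range[2] > 1 ||
      focus_z_range[1] >= focus_z_range[2]) {
    stopf("cohort_spec: focus_z_range must be an increasing interval within [0, 1]")
  }
  if (length(fmri_T_range) != 2 || fmri_T_range[1] > fmri_T_range[2] || fmri_T_range[1] < 1) {
    stopf("cohort_spec: fmri_T_range must be an increasing positive integer pair")
  }
  structure(list(n_per_class = n_per_class, modality = modality,
                 fmri_T_range = as.integer(fmri_T_range),
                 fmri_T_mode = as.integer(fmri_T_mode),
                 fmri_T_mode_prob = fmri_T_mode_prob,
                 effect_size = effect_size, noise_sd = noise_sd,
                 empty_slice_prob = empty_slice_prob,
                 focus_z_range = focus_z_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Ellipsoid brain mask.  The z semi-axis is deliberately elongated
# (0.75 Z) so that the whole axial range kept after the tail drop lies
# inside the brain: structurally empty slices are then injected only via
# empty_slice_prob, and every exported slice intersects the class foci.
brain_mask <- function(shape) {
  x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
  cx <- (shape[1] + 1) / 2; cy <- (shape[2] + 1) / 2; cz <- (shape[3] + 1) / 2
  rx <- 0.44 * shape[1]; ry <- 0.46 * shape[2]; rz <- 0.75 * shape[3]
  dx2 <- ((x - cx) / rx)^2
  dy2 <- ((y - cy) / ry)^2
  dz2 <- ((z - cz) / rz)^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  list(inside = r2 < 1, r2 = r2)
}

#' In-plane focus centers of one class (voxel coordinates)
#' @noRd
class_foci_xy <- function(shape, label) {
  cx <- (shape[1] + 1) / 2; cy <- (shape[2] + 1) / 2
  rx <- 0.44 * shape[1]; ry <- 0.46 * shape[2]
  th <- CLASS_FOCI_ANGLES[[label]] * pi / 180
  cbind(x = cx + FOCUS_RING_RADIUS * rx * cos(th),
        y = cy + FOCUS_RING_RADIUS * ry * sin(th))
}

class_signal_plane <- function(shape, label, effect_size) {
  foci <- class_foci_xy(shape, label)
  sig <- matrix(0, shape[1], shape[2])
  s <- FOCUS_SIGMA_FRAC * min(shape[1], shape[2])
  x <- seq_len(shape[1]); y <- seq_len(shape[2])
  for (i in seq_len(nrow(foci))) {
    sig <- sig + effect_size * outer(exp(-(x - foci[i, "x"])^2 / (2 * s^2)),
                                     exp(-(y - foci[i, "y"])^2 / (2 * s^2)))
  }
  sig
}

generate_subject_volume <- function(subject_id, label, spec) {
  shape <- if (spec$modality == "fmri") FMRI_SHAPE else SMRI_SHAPE
  stream <- derive_seed(spec$seed, subject_id)
  with_seed(stream, {
    Tn <- 1L
    if (spec$modality == "fmri") {
      Tn <- if (stats::runif(1) < spec$fmri_T_mode_prob) spec$fmri_T_mode
            else sample(spec$fmri_T_range[1]:spec$fmri_T_range[2], 1L)
    }
    msk <- brain_mask(shape)
    # baseline: smooth dome peaking at 100 inside the ellipsoid
    base3d <- ifelse(msk$inside, 100 * sqrt(pmax(1 - msk$r2, 0)), 0)
    # class foci: in-plane Gaussians over the configured z extent
    plane <- class_signal_plane(shape, label, spec$effect_size)
    zfrac <- (seq_len(shape[3]) - 1) / (shape[3] - 1)
    zind <- as.numeric(zfrac >= spec$focus_z_range[1] & zfrac <= spec$focus_z_range[2])
    sig3d <- outer(plane, zind) * (msk$inside + 0)
    clean <- base3d + sig3d
    mask_num <- msk$inside + 0
    if (spec$modality == "fmri") {
      vol <- array(0, c(shape, Tn))
      for (t in seq_len(Tn)) {
        vol[, , , t] <- (clean + stats::rnorm(prod(shape), sd = spec$noise_sd) * mask_num)
      }
    } else {
      vol <- clean + stats::rnorm(prod(shape), sd = spec$noise_sd) * mask_num
    }
    # empty axial slices (all time points)
    empty <- stats::runif(shape[3]) < spec$empty_slice_prob
    if (any(empty)) {
      if (spec$modality == "fmri") vol[, , empty, ] <- 0 else vol[, , empty] <- 0
    }
    structure(list(subject_id = subject_id, label = label,
                   modality = spec$modality, voxels = vol, T = Tn,
                   empty_slices = which(empty) - 1L),
              class = "subject_volume")
  })
}

#' Generate a synthetic cohort
#'
#' Each subject draws from an independent random stream derived from
#' `(seed, subject_id)`, so adding or removing subjects does not perturb
#' the others, and identical specs yield bitwise-identical voxel data.
#'
#' @param spec a [cohort_spec()].
#' @return list of `subject_volume` objects (fields `subject_id`, `label`,
#'   `modality`, `voxels`, `T`, `empty_slices`).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("generate_cohort: spec must be a cohort_spec")
  out <- list()
  for (label in names(spec$n_per_class)) {
    n <- spec$n_per_class[[label]]
    for (i in seq_len(n)) {
      sid <- sprintf("%s_%03d", label, i)
      out[[sid]] <- generate_subject_volume(sid, label, spec)
    }
  }
  out
}

#' Write a cohort to disk as NIfTI files plus a manifest
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` rather than `.nii`.
#' @return data.frame manifest (subject_id, label, modality, path, T),
#'   also written to `dir/cohort_manifest.csv`.
#' @export
write_cohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(sv) {
    ext <- if (gzip) ".nii.gz" else ".nii"
    path <- file.path(dir, paste0(sv$subject_id, ext))
    write_nifti(sv$voxels, path)
    data.frame(subject_id = sv$subject_id, label = sv$label,
               modality = sv$modality, path = path, T = sv$T,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "cohort_manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a cohort written by [write_cohort()] back into memory
#' @param dir cohort directory containing `cohort_manifest.csv`.
#' @return list of `subject_volume` objects.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "cohort_manifest.csv")
  if (!file.exists(mf)) stopf("read_cohort: no cohort manifest in %s", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    vol <- read_nifti(manifest$path[i])
    structure(list(subject_id = manifest$subject_id[i], label = manifest$label[i],
                   modality = manifest$modality[i], voxels = vol,
                   T = if (length(dim(vol)) == 4) dim(vol)[4] else 1L),
              class = "subject_volume")
  })
  names(out) <- manifest$subject_id
  out
}
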