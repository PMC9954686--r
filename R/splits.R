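# Subject-level stratified splitting and experiment schemes.
#
# Splitting is done once at subject level (all slices of a subject share a
# split, preventing slice leakage across sets) with the floor/floor/
# remainder convention per class: |train| = floor(0.8 n), |val| =
# floor(0.1 n), |test| = n - |train| - |val|.  This is the unique simple
# rounding that reproduces both published split triples: 54/99/131
# subjects -> 226/27/31 and 577/108/775 -> 1167/144/149.

#' Per-class split sizes under the floor/floor/remainder convention
#'
#' @param class_counts named integer vector of subjects per class.
#' @param fractions train/val/test fractions summing to 1.
#' @return matrix with one row per class and columns train/val/test.
#' @export
split_sizes <- function(class_counts, fractions = c(0.8, 0.1, 0.1)) {
  if (abs(sum(fractions) - 1) > 1e-9) stopf("split_sizes: fractions must sum to 1")
  if (length(fractions) != 3) stopf("split_sizes: need train/val/test fractions")
  n <- as.integer(class_counts)
  tr <- floor(fractions[1] * n)
  va <- floor(fractions[2] * n)
  te <- n - tr - va
  out <- cbind(train = tr, val = va, test = te)
  rownames(out) <- names(class_counts)
  out
}

#' Stratified subject-level 80/10/10 split
#'
#' Split sizes depend only on the class counts (not on the seed);
#' membership is chosen by a seeded shuffle within each class.
#'
#' @param subjects data.frame with columns `subject_id` and `label`, or a
#'   named character vector of labels (names = subject IDs).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed integer seed for the within-class shuffles.
#' @param min_class_size smallest class size accepted (default 3 so every
#'   split is nonempty); set to 1 to override.
#' @return object of class `split_spec`: data.frame (subject_id, label,
#'   split) with attributes `seed` and `fractions`.
#' @export
stratified_split <- function(subjects, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                             min_class_size = 3L) {
  if (is.character(subjects) || is.factor(subjects)) {
    subjects <- data.frame(subject_id = names(subjects), label = as.character(subjects),
                           stringsAsFactors = FALSE)
  }
  if (anyDuplicated(subjects$subject_id)) stopf("stratified_split: duplicated subject IDs")
  counts <- table(subjects$label)
  if (any(counts < min_class_size)) {
    stopf("stratified_split: class %s has fewer than %d subjects",
          names(counts)[which.min(counts)], min_class_size)
  }
  sizes <- split_sizes(as.integer(counts), fractions)
  rownames(sizes) <- names(counts)
  parts <- lapply(names(counts), function(cl) {
    ids <- subjects$subject_id[subjects$label == cl]
    ids <- with_seed(derive_seed(seed, cl), sample(ids))
    sz <- sizes[cl, ]
    data.frame(subject_id = ids, label = cl,
               split = rep(c("train", "val", "test"), times = sz),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$subject_id), ]
  rownames(out) <- NULL
  structure(out, seed = as.integer(seed), fractions = fractions,
            class = c("split_spec", "data.frame"))
}

SCHEME_NAMES <- c("AD_HC_MCI", "ADMCI_HC", "AD_HCMCI", "AD_HC", "HC_MCI")

#' Label-merging experiment schemes
#'
#' The five experiment schemes relabel the three diagnostic classes:
#' `AD_HC_MCI` (identity, 3-class), `ADMCI_HC` (AD and MCI merged vs HC),
#' `AD_HCMCI` (AD vs merged HC and MCI), `AD_HC` (MCI excluded), `HC_MCI`
#' (AD excluded).  Hyphens are accepted in place of underscores.
#'
#' @param name scheme name.
#' @return list with `name` and `label_map` (original label -> experiment
#'   label or `"EXCLUDE"`).
#' @export
experiment_scheme <- function(name) {
  key <- gsub("-", "_", toupper(name))
  map <- switch(key,
    AD_HC_MCI = c(AD = "AD", HC = "HC", MCI = "MCI"),
    ADMCI_HC  = c(AD = "ADMCI", HC = "HC", MCI = "ADMCI"),
    AD_HCMCI  = c(AD = "AD", HC = "HCMCI", MCI = "HCMCI"),
    AD_HC     = c(AD = "AD", HC = "HC", MCI = "EXCLUDE"),
    HC_MCI    = c(AD = "EXCLUDE", HC = "HC", MCI = "MCI"),
    stopf("experiment_scheme: unknown scheme '%s' (known: %s)", name,
          paste(SCHEME_NAMES, collapse = ", ")))
  list(name = key, label_map = map)
}

#' Apply an experiment scheme to a manifest or split table
#'
#' Labels are remapped according to the scheme; rows mapped to `EXCLUDE`
#' are dropped; the split assignment is left untouched, so the identical
#' splits are reused across experiments.
#'
#' @param manifest data.frame with a `label` column (and any others).
#' @param scheme an [experiment_scheme()] or scheme name.
#' @return the manifest with remapped labels.
#' @export
apply_scheme <- function(manifest, scheme) {
  if (is.character(scheme)) scheme <- experiment_scheme(scheme)
  bad <- setdiff(unique(manifest$label), names(scheme$label_map))
  if (length(bad) > 0) stopf("apply_scheme: unknown labels %s", paste(bad, collapse = ", "))
  new_label <- unname(scheme$label_map[manifest$label])
  keep <- new_label != "EXCLUDE"
  out <- manifest[keep, , drop = FALSE]
  out$label <- new_label[keep]
  if ("train_label" %in% names(out)) {
    out$train_label <- unname(scheme$label_map[out$train_label])
  }
  rownames(out) <- NULL
  out
}

#' Healthy-control noise challenge
#'
#' Relabels a chosen number of healthy-control training subjects as AD and
#' as MCI in the *training* ground truth only; evaluation keeps the true
#' labels (the challenge measures how training-label noise is handled, so
#' evaluation labels must stay clean).  Only HC subjects assigned to the
#' train split are eligible.
#'
#' @param split a `split_spec` (or data.frame with subject_id, label,
#'   split).
#' @param n_to_ad,n_to_mci numbers of HC training subjects to relabel.
#' @param seed seed for the subject selection.
#' @return the split table with an added/updated `train_label` column.
#' @export
insert_hc_noise <- function(split, n_to_ad = 0L, n_to_mci = 0L, seed = 1L) {
  if (n_to_ad < 0 || n_to_mci < 0) stopf("insert_hc_noise: counts must be >= 0")
  if (is.null(split$train_label)) split$train_label <- split$label
  hc_train <- split$subject_id[split$label == "HC" & split$split == "train"]
  need <- n_to_ad + n_to_mci
  if (need > length(hc_train)) {
    stopf("insert_hc_noise: requested %d HC subjects but only %d HC training subjects available",
          need, length(hc_train))
  }
  if (need == 0) return(split)
  chosen <- with_seed(derive_seed(seed, "hc_noise"), sample(hc_train, need))
  to_ad <- chosen[seq_len(n_to_ad)]
  to_mci <- if (n_to_mci > 0) chosen[n_to_ad + seq_len(n_to_mci)] else character()
  split$train_label[split$subject_id %in% to_ad] <- "AD"
  split$train_label[split$subject_id %in% to_mci] <- "MCI"
  split
}
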