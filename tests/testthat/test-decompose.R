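# Slice decomposition: count law against a brute-force oracle, tail drop,
# empty-slice filter, manifest construction, filename round trips.

brute_force_count <- function(vox, drop_tail = 10L) {
  if (length(dim(vox)) == 3) dim(vox) <- c(dim(vox), 1L)
  Z <- dim(vox)[3]; Tn <- dim(vox)[4]
  n <- 0L
  for (z in seq_len(Z - drop_tail)) {
    for (t in seq_len(Tn)) if (sum(vox[, , z, t]) != 0) n <- n + 1L
  }
  n
}

test_that("record count equals the brute-force nonzero-sum count", {
  for (seed in 1:3) {
    spec <- cohort_spec(c(AD = 1, HC = 1, MCI = 1), "fmri",
                        fmri_T_range = c(2, 4), fmri_T_mode = 3,
                        empty_slice_prob = 0.25, seed = seed)
    for (sv in generate_cohort(spec)) {
      rec <- decompose_volume(sv, decompose_params(), write = FALSE)
      expect_identical(nrow(rec), brute_force_count(sv$voxels))
      expect_true(all(rec$z <= dim(sv$voxels)[3] - 11L))
      expect_true(all(rec$sum_intensity != 0))
      expect_false(anyDuplicated(rec[, c("subject_id", "z", "t")]) > 0)
      # records in (z, t) lexicographic order
      expect_identical(order(rec$z, rec$t), seq_len(nrow(rec)))
    }
  }
})

test_that("a forced all-zero z plane is filtered for every time point", {
  spec <- cohort_spec(c(AD = 1), "fmri", fmri_T_range = c(3, 3),
                      fmri_T_mode = 3, fmri_T_mode_prob = 1,
                      empty_slice_prob = 0, seed = 4)
  sv <- generate_cohort(spec)$AD_001
  sv$voxels[, , 6, ] <- 0   # z index 5 (0-based)
  rec <- decompose_volume(sv, decompose_params(), write = FALSE)
  expect_false(any(rec$z == 5L))
  expect_identical(nrow(rec), brute_force_count(sv$voxels))
})

test_that("structural volumes yield Z - 10 slices and written PNGs round-trip", {
  fx <- small_smri_fixture()
  sv <- fx$cohort$AD_001
  rec <- fx$records[fx$records$subject_id == "AD_001", ]
  expect_identical(nrow(rec), 81L)          # 91 - 10, no empty slices
  expect_identical(sort(unique(rec$t)), 0L)
  # written slice equals the quantized raw plane
  r <- rec[10, ]
  win <- range(sv$voxels)
  oracle <- floor((sv$voxels[, , r$z + 1] - win[1]) / (win[2] - win[1]) * 255 + 0.5)
  expect_equal(png_read_gray(r$path), oracle, ignore_attr = TRUE)
})

test_that("drop_tail >= Z errors and params are validated", {
  spec <- cohort_spec(c(AD = 1), "smri", seed = 1)
  sv <- generate_cohort(spec)$AD_001
  expect_error(decompose_volume(sv, decompose_params(drop_tail = 91)), "drop_tail")
  expect_error(decompose_params(bit_depth = 12), "bit_depth")
  expect_error(decompose_params(drop_tail = -1), "drop_tail")
})

test_that("slice filenames encode and parse losslessly", {
  for (case in list(list("AD_001", 0L, 0L), list("HC_023", 34L, 139L),
                    list("subj-x", 7L, 5L))) {
    fn <- slice_filename(case[[1]], case[[2]], case[[3]])
    p <- parse_slice_filename(fn)
    expect_identical(p$subject_id, case[[1]])
    expect_identical(p$z, case[[2]])
    expect_identical(p$t, case[[3]])
  }
  expect_error(parse_slice_filename("garbage.png"), "unparseable")
})

test_that("build_manifest joins splits, validates subjects, handles empties", {
  fx <- small_smri_fixture()
  two <- fx$records[fx$records$subject_id %in% c("AD_001", "HC_001"), ]
  mani <- build_manifest(two, fx$split)
  expect_identical(nrow(mani), 162L)
  expect_identical(unique(mani$subject_id), c("AD_001", "HC_001"))  # grouped
  expect_named(mani, c("path", "subject_id", "label", "split", "z", "t"))
  expect_error(build_manifest(two, fx$split[fx$split$subject_id != "AD_001", ]),
               "missing from split")
  empty <- build_manifest(two[0, ], fx$split)
  expect_identical(nrow(empty), 0L)
})
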