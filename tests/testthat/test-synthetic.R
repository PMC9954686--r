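# Synthetic cohort generator: geometry, determinism, per-subject stream
# independence, separability oracle.

test_that("counts and shapes are forced by the spec", {
  spec <- cohort_spec(c(AD = 3, HC = 3, MCI = 3), "smri", seed = 1)
  co <- generate_cohort(spec)
  expect_length(co, 9L)
  for (sv in co) expect_identical(dim(sv$voxels), c(91L, 109L, 91L))
  spec_f <- cohort_spec(c(AD = 1, HC = 1, MCI = 1), "fmri",
                        fmri_T_range = c(4, 6), fmri_T_mode = 5, seed = 1)
  for (sv in generate_cohort(spec_f)) {
    d <- dim(sv$voxels)
    expect_identical(d[1:3], c(45L, 54L, 45L))
    expect_true(d[4] >= 4 && d[4] <= 6)
  }
})

test_that("identical spec and seed give bitwise-identical cohorts", {
  spec <- cohort_spec(c(AD = 1, HC = 1, MCI = 1), "fmri",
                      fmri_T_range = c(3, 4), fmri_T_mode = 3, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  for (nm in names(a)) expect_identical(a[[nm]]$voxels, b[[nm]]$voxels)
})

test_that("per-subject streams are independent of cohort composition", {
  s1 <- cohort_spec(c(AD = 1, HC = 1, MCI = 1), "smri", seed = 3)
  s2 <- cohort_spec(c(AD = 2, HC = 1, MCI = 1), "smri", seed = 3)
  a <- generate_cohort(s1)
  b <- generate_cohort(s2)
  expect_identical(a$HC_001$voxels, b$HC_001$voxels)
  expect_identical(a$AD_001$voxels, b$AD_001$voxels)
})

test_that("background outside the brain mask is zero and values are finite", {
  spec <- cohort_spec(c(AD = 1, HC = 0, MCI = 0), "smri", seed = 2)
  v <- generate_cohort(spec)$AD_001$voxels
  expect_true(all(is.finite(v)))
  expect_identical(v[1, 1, 1], 0)          # corner is far outside the ellipsoid
  expect_identical(v[1, 1, 45], 0)
  expect_gt(v[46, 55, 46], 50)             # center is bright
})

test_that("cohorts round-trip through NIfTI with geometry preserved", {
  spec <- cohort_spec(c(AD = 1, HC = 1, MCI = 0), "fmri",
                      fmri_T_range = c(3, 3), fmri_T_mode = 3,
                      fmri_T_mode_prob = 1, seed = 9)
  co <- generate_cohort(spec)
  dir <- tempfile("cohort_")
  manifest <- write_cohort(co, dir)
  expect_identical(nrow(manifest), 2L)
  back <- read_cohort(dir)
  for (nm in names(co)) {
    expect_identical(dim(back[[nm]]$voxels), dim(co[[nm]]$voxels))
    expect_lt(max(abs(back[[nm]]$voxels - co[[nm]]$voxels)), 1e-4)
  }
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(c(AD = 0, HC = 0, MCI = 0)), "zero subjects")
  expect_error(cohort_spec(c(AD = 1), modality = "pet"), "arg")
  expect_error(cohort_spec(c(AD = 1), noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(c(AD = 1), effect_size = -1), "effect_size")
  expect_error(cohort_spec(c(AD = 1), empty_slice_prob = 2), "empty_slice_prob")
  expect_error(cohort_spec(c(AD = 1), focus_z_range = c(0.5, 0.2)), "focus_z_range")
})

test_that("separability is monotone in effect size; zero effect is chance", {
  # independent oracle: multinomial logistic on the decomposed slice pixels
  fit_acc <- function(effect, seed) {
    spec <- cohort_spec(c(AD = 4, HC = 4, MCI = 4), "fmri",
                        fmri_T_range = c(2, 3), fmri_T_mode = 2,
                        fmri_T_mode_prob = 0.5, effect_size = effect,
                        noise_sd = 1, empty_slice_prob = 0, seed = seed)
    co <- generate_cohort(spec)
    rec <- decompose_cohort(co, write = FALSE)
    X <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
      sv <- co[[rec$subject_id[i]]]
      as.vector(sv$voxels[, , rec$z[i] + 1, rec$t[i] + 1])
    }))
    y <- factor(rec$label)
    n <- nrow(X)
    set.seed(seed)
    tr <- sample(n, round(0.7 * n))
    fit <- glmnet::glmnet(X[tr, ], y[tr], family = "multinomial", lambda = 0.01)
    mean(predict(fit, X[-tr, ], type = "class") == as.character(y[-tr]))
  }
  accs <- sapply(1:3, function(s) sapply(c(0, 3, 8), fit_acc, seed = s))
  avg <- rowMeans(accs)   # one mean accuracy per effect level
  expect_lte(avg[1], avg[2] + 0.05)
  expect_lte(avg[2], avg[3] + 0.05)
  expect_gt(avg[3], 0.9)
  expect_lt(abs(avg[1] - 1 / 3), 0.12)   # chance within ~4 binomial sd
})
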