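# Stratified splitting, experiment schemes, healthy-control noise
# insertion.

test_that("published split triples are reproduced exactly", {
  s <- split_sizes(c(AD = 54, HC = 99, MCI = 131))
  expect_identical(unname(colSums(s)), c(226, 27, 31))
  s2 <- split_sizes(c(AD = 577, HC = 108, MCI = 775))
  expect_identical(unname(colSums(s2)), c(1167, 144, 149))
  expect_identical(unname(split_sizes(c(X = 10))), cbind(8, 1, 1), ignore_attr = TRUE)
  expect_error(split_sizes(c(A = 10), fractions = c(0.8, 0.1, 0.2)), "sum to 1")
})

make_subjects <- function(counts) {
  do.call(rbind, lapply(names(counts), function(cl) {
    data.frame(subject_id = sprintf("%s_%02d", cl, seq_len(counts[[cl]])),
               label = cl, stringsAsFactors = FALSE)
  }))
}

test_that("sizes depend only on counts; membership on the seed; reruns reproduce", {
  subjects <- make_subjects(c(AD = 14, HC = 23, MCI = 33))
  a <- stratified_split(subjects, seed = 1)
  b <- stratified_split(subjects, seed = 2)
  c2 <- stratified_split(subjects, seed = 1)
  tab_a <- table(a$label, a$split)
  expect_identical(table(b$label, b$split), tab_a)
  expect_identical(unname(tab_a["AD", c("train", "val", "test")]),
                   c(11L, 1L, 2L))
  expect_false(identical(a$split, b$split))
  expect_identical(as.data.frame(a), as.data.frame(c2))
  # subject-level partition: disjoint and exhaustive
  expect_identical(sort(a$subject_id), sort(subjects$subject_id))
  expect_false(anyDuplicated(a$subject_id) > 0)
})

test_that("small classes are rejected unless overridden", {
  subjects <- make_subjects(c(AD = 2, HC = 5, MCI = 5))
  expect_error(stratified_split(subjects), "fewer than 3")
  expect_s3_class(stratified_split(subjects, min_class_size = 1), "split_spec")
})

test_that("experiment schemes remap labels and keep splits untouched", {
  sch <- experiment_scheme("ADMCI_HC")
  expect_identical(unname(sch$label_map[c("AD", "MCI", "HC")]),
                   c("ADMCI", "ADMCI", "HC"))
  mani <- data.frame(subject_id = c("a", "b", "c"),
                     label = c("AD", "MCI", "HC"),
                     split = c("train", "val", "test"),
                     stringsAsFactors = FALSE)
  out <- apply_scheme(mani, "ADMCI_HC")
  expect_identical(out$label, c("ADMCI", "ADMCI", "HC"))
  expect_identical(out$split, mani$split)
  # identity scheme
  expect_identical(apply_scheme(mani, "AD_HC_MCI")$label, mani$label)
  # exclusion drops subjects, keeps the rest's split assignment
  ah <- apply_scheme(mani, "AD-HC")
  expect_identical(ah$subject_id, c("a", "c"))
  expect_identical(ah$split, c("train", "test"))
  expect_error(experiment_scheme("AD_VS_EVERYONE"), "unknown scheme")
})

test_that("HC noise insertion relabels training ground truth only", {
  subjects <- make_subjects(c(AD = 10, HC = 20, MCI = 10))
  sp <- stratified_split(subjects, seed = 1)
  hc_train <- sum(sp$label == "HC" & sp$split == "train")  # 16
  # identity at zero
  expect_identical(insert_hc_noise(sp, 0, 0)$train_label, sp$label)
  ns <- insert_hc_noise(sp, n_to_ad = 5, n_to_mci = 3, seed = 2)
  tr <- ns[ns$split == "train", ]
  expect_identical(sum(tr$train_label == "AD") - sum(tr$label == "AD"), 5L)
  expect_identical(sum(tr$train_label == "MCI") - sum(tr$label == "MCI"), 3L)
  expect_identical(sum(tr$label == "HC") - sum(tr$train_label == "HC"), 8L)
  # evaluation ground truth (label) untouched
  expect_identical(ns$label, sp$label)
  # only training-split subjects relabeled
  expect_identical(ns$train_label[ns$split != "train"], ns$label[ns$split != "train"])
  expect_error(insert_hc_noise(sp, n_to_ad = hc_train + 1), "available")
  # reproducible
  expect_identical(insert_hc_noise(sp, 5, 3, seed = 2), ns)
})
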