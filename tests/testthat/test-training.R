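# Training regimen: schedule arithmetic, checkpoint selection, prediction
# contracts, reproducibility.  Convergence behavior lives in
# test-acceptance.R (criterion 6).

test_that("step decay follows lr0 * gamma^epoch", {
  tc <- train_config()      # published regimen: 3e-5, gamma 0.7, step 1
  expect_identical(tc$epochs, 40L)
  expect_identical(tc$batch_size, 64L)
  expect_equal(lr_at_epoch(tc, 0), 3e-5)
  expect_equal(lr_at_epoch(tc, 2), 3e-5 * 0.49)
  tc2 <- train_config(lr = 1e-3, gamma = 0.5, step_size = 2)
  expect_equal(lr_at_epoch(tc2, 3), 1e-3 * 0.5)
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(gamma = 0), "gamma")
  expect_error(train_config(lr = 0), "lr")
})

test_that("best-checkpoint selection maximizes val accuracy, earliest tie", {
  hist <- data.frame(epoch = 0:2, val_acc = c(0.5, 0.9, 0.7))
  ckpts <- data.frame(epoch = 0:2, path = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  expect_identical(select_best_checkpoint(hist, ckpts), "b")
  tie <- data.frame(epoch = 0:1, val_acc = c(0.9, 0.9))
  expect_identical(select_best_checkpoint(tie, ckpts), "a")
  expect_error(select_best_checkpoint(hist[0, ], ckpts), "empty history")
})

test_that("a short smoke run yields a complete history and valid predictions", {
  fx <- small_smri_fixture()
  model <- build_model(tiny_config("ovitad", image_size = 28L, patch_size = 14L),
                       seed = 1)
  fit <- train_model(model, fx$manifest,
                     train_config(epochs = 2, lr = 1e-4, seed = 1))
  expect_identical(nrow(fit$history), 2L)
  expect_named(fit$history, c("epoch", "lr", "train_loss", "train_acc",
                              "val_loss", "val_acc"))
  expect_equal(fit$history$lr, c(1e-4, 7e-5))
  expect_true(file.exists(fit$best))

  # untrained-model loss on balanced data is about ln(num_classes)
  expect_lt(abs(fit$history$train_loss[1] - log(3)) / log(3), 0.2)

  # the stored best checkpoint's recomputed val accuracy equals the
  # history's maximum
  va <- fx$manifest[fx$manifest$split == "val", ]
  preds <- predict_slices(fit$best, va)
  expect_equal(mean(preds$predicted_label == preds$true_label),
               max(fit$history$val_acc), tolerance = 1e-6)

  # slice predictions: probabilities sum to 1, argmax consistency,
  # determinism across calls
  pc <- paste0("prob_", c("AD", "HC", "MCI"))
  expect_equal(rowSums(preds[, pc]), rep(1, nrow(preds)), tolerance = 1e-5)
  expect_identical(preds$predicted_label,
                   c("AD", "HC", "MCI")[max.col(preds[, pc], "first")])
  expect_identical(predict_slices(fit$best, va), preds)

  # same seed and data reproduce the history exactly
  model2 <- build_model(tiny_config("ovitad", image_size = 28L, patch_size = 14L),
                        seed = 1)
  fit2 <- train_model(model2, fx$manifest,
                      train_config(epochs = 2, lr = 1e-4, seed = 1))
  expect_identical(fit2$history, fit$history)
})

test_that("degenerate manifests are rejected", {
  fx <- small_smri_fixture()
  model <- build_model(tiny_config("ovitad", image_size = 28L, patch_size = 14L),
                       seed = 1)
  no_val <- fx$manifest[fx$manifest$split != "val", ]
  expect_error(train_model(model, no_val, train_config(epochs = 1)),
               "empty validation")
  two_cls <- fx$manifest[fx$manifest$label != "MCI", ]
  expect_error(train_model(model, two_cls, train_config(epochs = 1)),
               "classes")
  fit <- train_model(model, fx$manifest, train_config(epochs = 1, seed = 1))
  bad <- fx$manifest[fx$manifest$split == "val", ][1, ]
  bad$path <- "/nonexistent/slice.png"
  expect_error(predict_slices(fit$best, bad),
               "missing image file: /nonexistent/slice.png")
})
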