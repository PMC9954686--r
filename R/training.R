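# Slice-level training.
#
# Published regimen: 40 epochs, batch size 64, Adam with learning rate
# 3e-5, step decay by gamma = 0.7 every epoch; cross-entropy loss; the
# best model is the epoch with the highest validation accuracy.

#' Training configuration
#'
#' @param epochs training epochs (published regimen: 40).
#' @param batch_size mini-batch size (64).
#' @param lr initial Adam learning rate (3e-5).
#' @param gamma multiplicative learning-rate decay (0.7).
#' @param step_size decay period in epochs (1).
#' @param seed seed controlling shuffling, dropout and initialization.
#' @param shuffle reshuffle training slices every epoch.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 40L, batch_size = 64L, lr = 3e-5,
                         gamma = 0.7, step_size = 1L, seed = 1L,
                         shuffle = TRUE) {
  if (epochs < 1) stopf("train_config: epochs must be >= 1")
  if (lr <= 0) stopf("train_config: lr must be > 0")
  if (gamma <= 0 || gamma > 1) stopf("train_config: gamma must be in (0, 1]")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, gamma = gamma, step_size = as.integer(step_size),
                 seed = as.integer(seed), shuffle = shuffle),
            class = "train_config")
}

#' Learning rate at a given (0-based) epoch under step decay
#' @param config a [train_config()].
#' @param epoch 0-based epoch index.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr * config$gamma^(epoch %/% config$step_size)
}

# image cache: path -> [0,1] grayscale matrix resized to the model input
load_slice_images <- function(paths, image_size) {
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stopf("missing image file: %s", paths[i])
    m <- png_read_gray(paths[i])
    maxv <- if (max(m) > 255) 65535 else 255
    out[[i]] <- resize_bilinear(m / maxv, image_size, image_size)
  }
  out
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (!is.null(dim(params[[nm]])) && is.null(dim(g))) dim(g) <- dim(params[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

manifest_labels <- function(manifest) {
  if ("train_label" %in% names(manifest)) {
    ifelse(manifest$split == "train", manifest$train_label, manifest$label)
  } else manifest$label
}

#' Train a model on a slice manifest
#'
#' Runs shuffled mini-batches with dropout active, decays the learning
#' rate by `gamma` each `step_size` epochs, evaluates validation accuracy
#' after every epoch, and writes a checkpoint whenever it improves.
#'
#' @param model a `vit_model` (e.g. from [build_model()]).
#' @param manifest slice manifest with columns path, subject_id, label,
#'   split (optionally `train_label` for the noise challenge).
#' @param config a [train_config()].
#' @param checkpoint_dir directory for checkpoint files (default: a
#'   session temporary directory).
#' @param verbose print one line per epoch.
#' @return list with `history` (per-epoch data.frame: epoch, lr,
#'   train_loss, train_acc, val_loss, val_acc), `checkpoints` (data.frame
#'   epoch/path for every improvement), `best` (best checkpoint path),
#'   `classes` (label order used for the logits).
#' @export
train_model <- function(model, manifest, config = train_config(),
                        checkpoint_dir = NULL, verbose = FALSE) {
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  va <- manifest[manifest$split == "val", , drop = FALSE]
  if (nrow(tr) == 0) stopf("train_model: empty training split")
  if (nrow(va) == 0) stopf("train_model: empty validation split")
  labels <- manifest_labels(manifest)
  classes <- sort(unique(labels))
  if (length(classes) != model$config$num_classes) {
    stopf("train_model: manifest has %d classes but the model expects %d",
          length(classes), model$config$num_classes)
  }
  checkpoint_dir <- checkpoint_dir %||% tempfile("ckpt_")
  dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  sz <- model$config$image_size
  tr_y <- match(labels[manifest$split == "train"], classes)
  va_y <- match(labels[manifest$split == "val"], classes)
  tr_imgs <- patchify_cache(load_slice_images(tr$path, sz), model$config)
  va_imgs <- patchify_cache(load_slice_images(va$path, sz), model$config)

  opt <- adam_init(model$params)
  history <- data.frame()
  ckpts <- data.frame(epoch = integer(), val_acc = numeric(), path = character())
  best_acc <- -Inf; best_path <- NULL
  set.seed(derive_seed(config$seed, "train"))
  n <- nrow(tr)
  for (epoch in 0:(config$epochs - 1L)) {
    lr <- lr_at_epoch(config, epoch)
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      out <- vit_forward(model, tr_imgs[idx], training = TRUE)
      loss <- ad_softmax_crossentropy(out$tape, out$logits_node, tr_y[idx])
      ad_backward(out$tape, loss)
      grads <- lapply(out$leafs, function(l) l$grad)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + loss$value * length(idx)
      ep_correct <- ep_correct + sum(max.col(out$logits) == tr_y[idx])
    }
    vl <- eval_images(model, va_imgs, va_y, config$batch_size)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = vl$loss, val_acc = vl$acc))
    if (verbose) {
      message(sprintf("epoch %2d lr %.3g train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, lr, ep_loss / n, ep_correct / n, vl$loss, vl$acc))
    }
    if (vl$acc > best_acc) {
      best_acc <- vl$acc
      best_path <- file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch))
      save_checkpoint(model, best_path, epoch = epoch, val_acc = vl$acc,
                      classes = classes, train_seed = config$seed)
      ckpts <- rbind(ckpts, data.frame(epoch = epoch, val_acc = vl$acc,
                                       path = best_path, stringsAsFactors = FALSE))
    }
  }
  list(history = history, checkpoints = ckpts, best = best_path, classes = classes,
       model = model)
}

eval_images <- function(model, imgs, y, batch_size = 64L) {
  n <- length(imgs)
  loss <- 0; correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    logits <- vit_forward(model, imgs[idx], training = FALSE)$logits
    P <- softmax_rows(logits)
    loss <- loss - sum(log(pmax(P[cbind(seq_along(idx), y[idx])], 1e-300)))
    correct <- correct + sum(max.col(logits) == y[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the weights together with the architecture
#' configuration, class order and provenance seeds, so it reloads into an
#' identical model.
#'
#' @param model a `vit_model`.
#' @param path checkpoint file (RDS).
#' @param ... further fields stored alongside (epoch, val_acc, classes...).
#' @export
save_checkpoint <- function(model, path, ...) {
  saveRDS(list(config = model$config, params = model$params,
               module = model$module, meta = list(...)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("load_checkpoint: no such file: %s", path)
  ck <- readRDS(path)
  model <- structure(list(config = ck$config, params = ck$params, module = ck$module),
                     class = "vit_model")
  list(model = model, meta = ck$meta)
}

#' Select the best checkpoint by validation accuracy
#'
#' Ties break toward the earliest epoch.
#'
#' @param history per-epoch history data.frame with `epoch` and `val_acc`.
#' @param checkpoints data.frame with `epoch` and `path` columns.
#' @return the winning checkpoint path (row of `checkpoints`).
#' @export
select_best_checkpoint <- function(history, checkpoints) {
  if (is.null(history) || nrow(history) == 0) stopf("select_best_checkpoint: empty history")
  best_epoch <- history$epoch[which.max(history$val_acc)]  # which.max = earliest tie
  row <- checkpoints[checkpoints$epoch == best_epoch, , drop = FALSE]
  if (nrow(row) == 0) stopf("select_best_checkpoint: no checkpoint for best epoch %d", best_epoch)
  row$path[1]
}

#' Slice-level prediction with class probabilities
#'
#' Deterministic (dropout off): repeated calls on the same checkpoint and
#' rows give identical output.
#'
#' @param checkpoint a checkpoint path or the list from [load_checkpoint()].
#' @param manifest_subset manifest rows to predict (path, subject_id,
#'   label, z, t).
#' @param batch_size prediction batch size.
#' @return data.frame: subject_id, z, t, true_label, predicted_label and
#'   one `prob_<class>` column per class (softmax of the logits).
#' @export
predict_slices <- function(checkpoint, manifest_subset, batch_size = 64L) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  model <- checkpoint$model
  classes <- checkpoint$meta$classes
  if (is.null(classes)) stopf("predict_slices: checkpoint lacks a class order")
  imgs <- load_slice_images(manifest_subset$path, model$config$image_size)
  n <- length(imgs)
  probs <- matrix(0, n, length(classes))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs[idx, ] <- softmax_rows(vit_forward(model, imgs[idx], training = FALSE)$logits)
  }
  colnames(probs) <- paste0("prob_", classes)
  out <- data.frame(subject_id = manifest_subset$subject_id,
                    z = manifest_subset$z, t = manifest_subset$t,
                    true_label = manifest_subset$label,
                    predicted_label = classes[max.col(probs, ties.method = "first")],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs))
}
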