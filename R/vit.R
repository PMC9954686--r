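# Vision transformer classifiers.
#
# One configuration type describes four variants sharing a common trunk
# (patch embedding -> class token -> positional embedding -> pre-norm
# transformer layers -> LayerNorm + linear classifier head):
#   vanilla  - standard multi-head self-attention (16 heads at 224 input;
#              the "224-8" baseline is the same config with 8 heads);
#   deepvit  - re-attention: post-softmax maps mixed across heads by a
#              learnable H x H matrix, renormalized over the head axis;
#   cait     - self-attention layers over patch tokens only, followed by
#              class-attention layers in which only the class token
#              queries; talking-heads mixing and LayerScale residual
#              gains;
#   ovitad   - the optimized reduced-input variant: 56 x 56 (fMRI) or
#              112 x 112 (structural) input, 8 heads, otherwise vanilla.
#
# Widths left unstated by the published architecture (patch size, embedding
# width, head width, head internals) are pinned by matching the published
# trainable-parameter table exactly; see solve_width_config().

#' Vision transformer configuration
#'
#' Defaults reproduce the published parameter counts: embedding width
#' 1024, head width 64, MLP width 2048, depth 6 (CaIT: 12 self-attention
#' + 2 class-attention layers), patch 32 at 224 x 224 input and patch 14
#' at 56 x 56 (28 at 112 x 112).
#'
#' @param variant one of `"vanilla"`, `"deepvit"`, `"cait"`, `"ovitad"`.
#' @param image_size input side length in pixels (square input, 3
#'   channels; grayscale slices are replicated across channels and resized
#'   bilinearly at load time).
#' @param patch_size patch side length; must divide `image_size`.
#' @param embed_dim token embedding width.
#' @param depth number of self-attention transformer layers.
#' @param heads attention heads.
#' @param head_dim per-head width.
#' @param mlp_dim feed-forward hidden width.
#' @param num_classes output classes.
#' @param dropout,emb_dropout dropout rates (default 0.1 each).
#' @param cait_cls_depth class-attention layers (cait only).
#' @param channels input channels (3).
#' @return object of class `vit_config`.
#' @export
vit_config <- function(variant = c("vanilla", "deepvit", "cait", "ovitad"),
                       image_size = NULL, patch_size = NULL,
                       embed_dim = 1024L, depth = NULL, heads = NULL,
                       head_dim = 64L, mlp_dim = 2048L, num_classes = 3L,
                       dropout = 0.1, emb_dropout = 0.1,
                       cait_cls_depth = 2L, channels = 3L) {
  variant <- match.arg(variant)
  image_size <- image_size %||% switch(variant, ovitad = 56L, 224L)
  patch_size <- patch_size %||%
    if (variant == "ovitad") {
      if (image_size %% 4 == 0) image_size %/% 4L else stopf("vit_config: give patch_size")
    } else 32L
  depth <- depth %||% switch(variant, cait = 12L, 6L)
  heads <- heads %||% switch(variant, ovitad = 8L, 16L)
  if (image_size %% patch_size != 0) {
    stopf("vit_config: image_size %d not divisible by patch_size %d", image_size, patch_size)
  }
  if (depth < 1 || heads < 1 || embed_dim < 1 || head_dim < 1 || mlp_dim < 1) {
    stopf("vit_config: depth, heads and widths must be >= 1")
  }
  n_patches <- (image_size %/% patch_size)^2
  structure(list(variant = variant, image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size), channels = as.integer(channels),
                 embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 heads = as.integer(heads), head_dim = as.integer(head_dim),
                 mlp_dim = as.integer(mlp_dim), num_classes = as.integer(num_classes),
                 dropout = dropout, emb_dropout = emb_dropout,
                 cait_cls_depth = if (variant == "cait") as.integer(cait_cls_depth) else 0L,
                 n_patches = as.integer(n_patches)),
            class = "vit_config")
}

#' Canonical configurations of the five published model variants
#'
#' `"vit_224_8"` is the vanilla baseline with 8 heads instead of 16.
#' @param name variant name, additionally accepting `"vit_224_8"` /
#'   `"ViT-224-8"` / `"vit-vanilla"` spellings.
#' @param num_classes output classes.
#' @param image_size override for the ovitad input side (56 fMRI, 112 sMRI).
#' @return a [vit_config()].
#' @export
canonical_config <- function(name, num_classes = 3L, image_size = NULL) {
  key <- gsub("-", "_", tolower(name))
  switch(key,
    vit_vanilla = , vanilla = vit_config("vanilla", num_classes = num_classes),
    vit_224_8 = vit_config("vanilla", heads = 8L, num_classes = num_classes),
    deepvit = vit_config("deepvit", num_classes = num_classes),
    cait = vit_config("cait", num_classes = num_classes),
    ovitad = vit_config("ovitad", image_size = image_size %||% 56L,
                        num_classes = num_classes),
    stopf("canonical_config: unknown model '%s'", name))
}

# parameter inventory: name, dims, module? (bare tensors - positional
# embedding, class token, re-attention/talking-heads mixes, LayerScale
# gains - live outside torch-style modules and are excluded from the
# published counts)
param_inventory <- function(config) {
  d <- config$embed_dim; H <- config$heads; dh <- config$head_dim
  inner <- H * dh; mlp <- config$mlp_dim
  patch_dim <- config$channels * config$patch_size^2
  N <- config$n_patches
  inv <- list(
    list("patch_w", c(patch_dim, d), TRUE),
    list("patch_b", d, TRUE),
    list("pos", c(if (config$variant == "cait") N else N + 1L, d), FALSE),
    list("cls", c(1L, d), FALSE)
  )
  layer_inv <- function(prefix, n_layers, class_attn = FALSE) {
    out <- list()
    for (l in seq_len(n_layers)) {
      p <- function(nm) sprintf("%s%d.%s", prefix, l, nm)
      out <- c(out, list(
        list(p("ln1_g"), d, TRUE), list(p("ln1_b"), d, TRUE)))
      if (config$variant == "cait") {
        out <- c(out, list(
          list(p("w_q"), c(d, inner), TRUE),
          list(p("w_kv"), c(d, 2L * inner), TRUE),
          list(p("mix_pre"), c(H, H), FALSE),
          list(p("mix_post"), c(H, H), FALSE)))
      } else {
        out <- c(out, list(list(p("w_qkv"), c(d, 3L * inner), TRUE)))
      }
      if (config$variant == "deepvit") {
        out <- c(out, list(
          list(p("reattn_theta"), c(H, H), FALSE),
          list(p("reattn_g"), H, TRUE),
          list(p("reattn_b"), H, TRUE)))
      }
      out <- c(out, list(
        list(p("w_out"), c(inner, d), TRUE), list(p("out_b"), d, TRUE),
        list(p("ln2_g"), d, TRUE), list(p("ln2_b"), d, TRUE),
        list(p("ff_w1"), c(d, mlp), TRUE), list(p("ff_b1"), mlp, TRUE),
        list(p("ff_w2"), c(mlp, d), TRUE), list(p("ff_b2"), d, TRUE)))
      if (config$variant == "cait") {
        out <- c(out, list(
          list(p("ls1"), d, FALSE), list(p("ls2"), d, FALSE)))
      }
    }
    out
  }
  inv <- c(inv, layer_inv("layers.", config$depth))
  if (config$variant == "cait") {
    inv <- c(inv, layer_inv("cls_layers.", config$cait_cls_depth, class_attn = TRUE))
  }
  c(inv, list(
    list("head_ln_g", d, TRUE), list("head_ln_b", d, TRUE),
    list("head_w", c(d, config$num_classes), TRUE),
    list("head_b", config$num_classes, TRUE)))
}

#' Build a model from a configuration
#'
#' Weight matrices are initialized from N(0, 1/fan_in) (the torch Linear
#' convention, which keeps activation scale constant through the random
#' network); positional embedding and class token from N(0, 0.02^2);
#' LayerNorm gains 1, offsets and biases 0; LayerScale gains 0.1; head
#' mixing matrices from N(0, 1/heads).  Reproducible from `seed`.
#'
#' @param config a [vit_config()].
#' @param seed initialization seed.
#' @return object of class `vit_model` with elements `config`, `params`
#'   (named list of arrays) and `module` (logical vector marking module
#'   weights vs bare tensors).
#' @export
build_model <- function(config, seed = 0L) {
  if (!inherits(config, "vit_config")) stopf("build_model: config must be a vit_config")
  inv <- param_inventory(config)
  params <- list()
  module <- logical(length(inv))
  with_seed(derive_seed(seed, "init"), {
    for (i in seq_along(inv)) {
      nm <- inv[[i]][[1]]; dims <- inv[[i]][[2]]
      n <- prod(dims)
      val <- if (grepl("_g$", nm)) rep(1, n)            # LayerNorm gains
        else if (grepl("_b[12]?$", nm)) rep(0, n)       # biases / LN offsets
        else if (grepl("(^|\\.)ls[12]$", nm)) rep(0.1, n)  # LayerScale
        else if (nm %in% c("pos", "cls")) stats::rnorm(n, sd = 0.02)
        else if (length(dims) > 1) stats::rnorm(n, sd = 1 / sqrt(dims[1]))  # fan-in
        else stats::rnorm(n, sd = 0.02)
      params[[nm]] <- if (length(dims) > 1) matrix(val, dims[1], dims[2]) else val
      module[i] <- inv[[i]][[3]]
    }
  })
  names(module) <- names(params)
  structure(list(config = config, params = params, module = module),
            class = "vit_model")
}

#' Count trainable parameters
#'
#' `scope = "modules"` counts module weights only (the convention of the
#' published table, whose counting tool does not see bare tensors such as
#' the positional embedding, class token, re-attention mixing matrix,
#' talking-heads mixes and LayerScale gains); `scope = "all"` counts every
#' learnable scalar.
#'
#' @param model a `vit_model` (or a `vit_config`, counted analytically).
#' @param scope `"modules"` (default, published convention) or `"all"`.
#' @return integer-valued count (as double to avoid 32-bit overflow).
#' @export
count_trainable_parameters <- function(model, scope = c("modules", "all")) {
  scope <- match.arg(scope)
  if (inherits(model, "vit_config")) {
    inv <- param_inventory(model)
    keep <- vapply(inv, `[[`, logical(1), 3) | scope == "all"
    return(sum(vapply(inv[keep], function(e) prod(e[[2]]), numeric(1))))
  }
  if (!inherits(model, "vit_model")) stopf("count_trainable_parameters: need a vit_model or vit_config")
  keep <- model$module | scope == "all"
  sum(vapply(model$params[keep], function(p) length(p), numeric(1)))
}

#' Enumerate width configurations matching a target parameter count
#'
#' Searches the free architectural fields (patch size, embedding width,
#' head width) over a finite grid and returns every configuration whose
#' exact module-scope count equals `target_count`.  Used to pin the
#' internals the published description leaves open.
#'
#' @param target_count target number of trainable parameters.
#' @param fixed named list of [vit_config()] arguments held fixed
#'   (must include `variant`; `image_size`, `heads`, `depth` etc.).
#' @param search named list of candidate vectors for `patch_size`,
#'   `embed_dim`, `head_dim`.
#' @param scope counting scope, see [count_trainable_parameters()].
#' @return list of matching `vit_config`s (empty if no solution).
#' @export
solve_width_config <- function(target_count,
                               fixed = list(variant = "vanilla", image_size = 224L),
                               search = list(patch_size = c(8L, 14L, 16L, 28L, 32L, 56L),
                                             embed_dim = c(512L, 768L, 1024L),
                                             head_dim = c(32L, 64L)),
                               scope = "modules") {
  grid <- expand.grid(patch_size = search$patch_size,
                      embed_dim = search$embed_dim,
                      head_dim = search$head_dim)
  hits <- list()
  for (i in seq_len(nrow(grid))) {
    args <- c(fixed, as.list(grid[i, ]))
    if (args$image_size %% args$patch_size != 0) next
    cfg <- try(do.call(vit_config, args), silent = TRUE)
    if (inherits(cfg, "try-error")) next
    if (count_trainable_parameters(cfg, scope) == target_count) {
      hits[[length(hits) + 1L]] <- cfg
    }
  }
  hits
}

# ---- forward pass ----------------------------------------------------------

#' Cut an image matrix into flattened patch rows
#'
#' Pixel intensities in `[0, 1]` are standardized with the fixed affine
#' `(x - 0.5) / 0.5` (the torchvision grayscale convention), the image is
#' replicated to `channels` channels, and each patch is flattened in
#' (row, column, channel) order, patches ordered row-major over the patch
#' grid.
#' @noRd
patchify <- function(img, patch_size, channels = 3L) {
  img <- (img - 0.5) / 0.5
  s <- nrow(img)
  np <- s %/% patch_size
  idx <- seq_len(patch_size)
  out <- matrix(0, np * np, patch_size^2 * channels)
  k <- 1L
  for (py in seq_len(np)) {
    for (px in seq_len(np)) {
      patch <- img[(py - 1L) * patch_size + idx, (px - 1L) * patch_size + idx]
      out[k, ] <- rep(as.vector(patch), channels)
      k <- k + 1L
    }
  }
  out
}

prepare_batch <- function(images, config) {
  P <- lapply(images, function(im) {
    if (isTRUE(attr(im, "patchified"))) return(im)
    if (nrow(im) != config$image_size || ncol(im) != config$image_size) {
      im <- resize_bilinear(im, config$image_size, config$image_size)
    }
    patchify(im, config$patch_size, config$channels)
  })
  do.call(rbind, P)
}

# precompute patch rows once per dataset (trainer fast path)
patchify_cache <- function(images, config) {
  lapply(images, function(im) {
    if (nrow(im) != config$image_size || ncol(im) != config$image_size) {
      im <- resize_bilinear(im, config$image_size, config$image_size)
    }
    structure(patchify(im, config$patch_size, config$channels), patchified = TRUE)
  })
}

# shared transformer sublayers; `x` holds B blocks of Tt tokens
vit_layer_forward <- function(tape, x, leafs, prefix, config, B, Tt, training,
                              store = NULL, context = NULL, Tk = Tt) {
  d <- config$embed_dim; H <- config$heads; dh <- config$head_dim
  L <- function(nm) leafs[[paste0(prefix, nm)]]
  xn <- ad_layernorm(tape, x, L("ln1_g"), L("ln1_b"))
  if (config$variant == "cait") {
    # queries from the (pre-normed) primary tokens; in the class stage the
    # keys/values come from the raw (patch, cls) context
    q <- ad_matmul(tape, xn, L("w_q"))
    kv <- ad_matmul(tape, if (is.null(context)) xn else context, L("w_kv"))
    inner <- H * dh
    k <- ad_rows_cols(tape, kv, 1:inner)
    v <- ad_rows_cols(tape, kv, inner + 1:inner)
    att <- ad_attend(tape, q, k, v, B, H, Tq = Tt, Tk = Tk, dh = dh,
                     variant = "talking",
                     extra = list(mix_pre = L("mix_pre"), mix_post = L("mix_post")),
                     store = store)
  } else {
    qkv <- ad_matmul(tape, xn, L("w_qkv"))
    inner <- H * dh
    q <- ad_rows_cols(tape, qkv, 1:inner)
    k <- ad_rows_cols(tape, qkv, inner + 1:inner)
    v <- ad_rows_cols(tape, qkv, 2L * inner + 1:inner)
    att <- if (config$variant == "deepvit") {
      ad_attend(tape, q, k, v, B, H, Tq = Tt, Tk = Tt, dh = dh,
                variant = "reattention",
                extra = list(theta = L("reattn_theta"),
                             ln_gamma = L("reattn_g"), ln_beta = L("reattn_b")),
                store = store)
    } else {
      ad_attend(tape, q, k, v, B, H, Tq = Tt, Tk = Tt, dh = dh,
                variant = "softmax", store = store)
    }
  }
  proj <- ad_bias(tape, ad_matmul(tape, att, L("w_out")), L("out_b"))
  proj <- ad_dropout(tape, proj, config$dropout, training)
  if (config$variant == "cait") proj <- ad_colscale(tape, proj, L("ls1"))
  x <- ad_add(tape, x, proj)
  xn2 <- ad_layernorm(tape, x, L("ln2_g"), L("ln2_b"))
  h1 <- ad_gelu(tape, ad_bias(tape, ad_matmul(tape, xn2, L("ff_w1")), L("ff_b1")))
  h1 <- ad_dropout(tape, h1, config$dropout, training)
  h2 <- ad_bias(tape, ad_matmul(tape, h1, L("ff_w2")), L("ff_b2"))
  h2 <- ad_dropout(tape, h2, config$dropout, training)
  if (config$variant == "cait") h2 <- ad_colscale(tape, h2, L("ls2"))
  ad_add(tape, x, h2)
}

# column slice as an autodiff op
ad_rows_cols <- function(tape, x, cols) {
  ad_node(tape, x$value[, cols, drop = FALSE], list(x), function(nd) {
    gx <- matrix(0, nrow(nd$parents[[1]]$value), ncol(nd$parents[[1]]$value))
    gx[, cols] <- nd$grad
    ad_accum(nd$parents[[1]], gx)
  })
}

#' Forward pass of a vision transformer
#'
#' @param model a `vit_model`.
#' @param images list of grayscale image matrices in `[0, 1]` (resized to
#'   the configured input internally).
#' @param training apply dropout (TRUE) or run deterministically (FALSE).
#' @param capture_attention also return the post-softmax attention maps of
#'   every layer and head.
#' @param tape optionally, an existing tape (used by the trainer).
#' @return list with `logits` (B x num_classes), `fc_features`
#'   (B x embed_dim, the normalized class-token embedding feeding the
#'   classifier), optionally `attention` (list over layers of lists over
#'   heads of per-image map lists), and internals used by the trainer.
#' @export
vit_forward <- function(model, images, training = FALSE,
                        capture_attention = FALSE, tape = NULL) {
  config <- model$config
  B <- length(images)
  tape <- tape %||% ad_tape()
  leafs <- lapply(model$params, function(p) ad_leaf(tape, p))
  X <- prepare_batch(images, config)
  N <- config$n_patches
  x <- ad_bias(tape, ad_matmul(tape, ad_leaf(tape, X), leafs$patch_w), leafs$patch_b)
  attn <- if (capture_attention) list() else NULL
  if (config$variant == "cait") {
    Tt <- N
    x <- ad_add_pos(tape, x, leafs$pos, B, Tt)
    x <- ad_dropout(tape, x, config$emb_dropout, training)
    for (l in seq_len(config$depth)) {
      store <- if (capture_attention) new.env(parent = emptyenv()) else NULL
      x <- vit_layer_forward(tape, x, leafs, sprintf("layers.%d.", l), config,
                             B, Tt, training, store = store)
      if (capture_attention) attn[[l]] <- store$maps
    }
    # class stage: cls token attends over (patch tokens, cls)
    cls <- ad_repeat_rows(tape, leafs$cls, B)  # B x d: one cls row per image
    for (l in seq_len(config$cait_cls_depth)) {
      store <- if (capture_attention) new.env(parent = emptyenv()) else NULL
      ctx <- ad_interleave_ctx(tape, x, cls, B, N)
      cls <- vit_layer_forward(tape, cls, leafs, sprintf("cls_layers.%d.", l), config,
                               B, 1L, training, store = store,
                               context = ctx, Tk = N + 1L)
      if (capture_attention) attn[[config$depth + l]] <- store$maps
    }
    pooled <- cls
  } else {
    Tt <- N + 1L
    x <- ad_prepend_cls(tape, x, leafs$cls, B, N)
    x <- ad_add_pos(tape, x, leafs$pos, B, Tt)
    x <- ad_dropout(tape, x, config$emb_dropout, training)
    for (l in seq_len(config$depth)) {
      store <- if (capture_attention) new.env(parent = emptyenv()) else NULL
      x <- vit_layer_forward(tape, x, leafs, sprintf("layers.%d.", l), config,
                             B, Tt, training, store = store)
      if (capture_attention) attn[[l]] <- store$maps
    }
    pooled <- ad_rows(tape, x, (seq_len(B) - 1L) * Tt + 1L)
  }
  feat <- ad_layernorm(tape, pooled, leafs$head_ln_g, leafs$head_ln_b)
  logits <- ad_bias(tape, ad_matmul(tape, feat, leafs$head_w), leafs$head_b)
  list(logits = logits$value, fc_features = feat$value, attention = attn,
       tape = tape, leafs = leafs, logits_node = logits)
}

# replicate a 1 x d parameter row B times
ad_repeat_rows <- function(tape, p, B) {
  ad_node(tape, matrix(p$value, B, ncol(p$value), byrow = TRUE), list(p), function(nd) {
    ad_accum(nd$parents[[1]], matrix(colSums(nd$grad), 1))
  })
}

# per-image context rows (patch tokens then the cls row) for class-attention
ad_interleave_ctx <- function(tape, x, cls, B, N) {
  d <- ncol(x$value)
  Tk <- N + 1L
  x_out <- (rep(seq_len(B), each = N) - 1L) * Tk + rep(seq_len(N), B)
  cls_out <- seq_len(B) * Tk
  val <- matrix(0, B * Tk, d)
  val[x_out, ] <- x$value
  val[cls_out, ] <- cls$value
  ad_node(tape, val, list(x, cls), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad[x_out, , drop = FALSE])
    ad_accum(nd$parents[[2]], nd$grad[cls_out, , drop = FALSE])
  })
}

#' Predicted class probabilities for a batch of images
#' @param model a `vit_model`.
#' @param images list of grayscale matrices in `[0, 1]`.
#' @return B x num_classes matrix of softmax probabilities.
#' @export
predict_proba <- function(model, images) {
  softmax_rows(vit_forward(model, images, training = FALSE)$logits)
}

#' Standalone re-attention head mixing
#'
#' Mixes a stack of post-softmax per-head attention maps across heads with
#' a learnable H x H matrix: `mixed[h'] = sum_h theta[h', h] * maps[h]`,
#' optionally renormalizing over the head axis (LayerNorm, as used inside
#' the deepvit variant).
#'
#' @param head_scores list of H square matrices (post-softmax maps), or a
#'   3D array H x N' x N'.
#' @param theta H x H mixing matrix.
#' @param renormalize apply the across-head LayerNorm (gain 1, offset 0).
#' @return list of H mixed maps.
#' @export
reattention <- function(head_scores, theta, renormalize = FALSE) {
  if (is.array(head_scores) && length(dim(head_scores)) == 3) {
    head_scores <- lapply(seq_len(dim(head_scores)[1]), function(h) head_scores[h, , ])
  }
  H <- length(head_scores)
  if (!is.matrix(theta) || nrow(theta) != H || ncol(theta) != H) {
    stopf("reattention: theta must be %d x %d", H, H)
  }
  dims <- dim(head_scores[[1]])
  Smat <- vapply(head_scores, as.vector, numeric(prod(dims)))
  M <- Smat %*% t(theta)
  if (renormalize) {
    mu <- rowMeans(M); mc <- M - mu
    M <- mc / sqrt(rowMeans(mc * mc) + 1e-5)
  }
  lapply(seq_len(H), function(h) matrix(M[, h], dims[1], dims[2]))
}

#' Standalone class-attention update (CaIT class stage)
#'
#' The class token emits the only query and attends over the patch tokens
#' plus itself; patch tokens are not updated.  This mirrors one
#' class-attention sublayer with plain softmax attention and, optionally,
#' no residual path (for analytical checks).
#'
#' @param patch_tokens N x d matrix.
#' @param cls_token length-d vector (or 1 x d matrix).
#' @param w_q,w_kv,w_out projection matrices (d x inner, d x 2 inner,
#'   inner x d); defaults are identity-like single-head maps.
#' @param heads,head_dim head layout of the projections.
#' @param residual add the residual path (default TRUE).
#' @return list with `cls` (updated 1 x d class token), `weights`
#'   (attention row over the N+1 context tokens), `patch_tokens`
#'   (unchanged).
#' @export
class_attention_forward <- function(patch_tokens, cls_token,
                                    w_q = NULL, w_kv = NULL, w_out = NULL,
                                    heads = 1L, head_dim = ncol(patch_tokens),
                                    residual = TRUE) {
  d <- ncol(patch_tokens)
  inner <- heads * head_dim
  w_q <- w_q %||% diag(1, d, inner)
  w_kv <- w_kv %||% cbind(diag(1, d, inner), diag(1, d, inner))
  w_out <- w_out %||% diag(1, inner, d)
  cls <- matrix(as.numeric(cls_token), 1, d)
  ctx <- rbind(patch_tokens, cls)
  q <- cls %*% w_q
  kv <- ctx %*% w_kv
  k <- kv[, 1:inner, drop = FALSE]; v <- kv[, inner + 1:inner, drop = FALSE]
  scale <- 1 / sqrt(head_dim)
  upd <- matrix(0, 1, inner)
  wts <- matrix(0, heads, nrow(ctx))
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * head_dim + seq_len(head_dim)
    A <- softmax_rows(q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) * scale)
    wts[h, ] <- A
    upd[, cols] <- A %*% v[, cols, drop = FALSE]
  }
  out <- upd %*% w_out
  if (residual) out <- out + cls
  list(cls = out, weights = wts, patch_tokens = patch_tokens)
}
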