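# Attention-map extraction and global attention feature maps.
#
# For a trained model and one input slice, the per-layer, per-head
# post-softmax attention maps form a depth x heads grid ((N+1) x (N+1)
# token maps; 6 x 8 of 17 x 17 for the optimized 56-input variant).  The
# global attention feature map (GAFM) multiplies each pixel of the
# resized input by the sum of the final fully connected feature vector
# and min-max normalizes the result to the 0-255 range.  As defined, the
# normalized map depends on the feature vector only through the sign of
# its sum (positive scalars cancel under min-max normalization); the
# formula is implemented exactly as published, and this reduction is
# pinned by a regression test rather than "fixed".

#' Extract the post-softmax attention maps of every layer and head
#'
#' @param model a `vit_model`, checkpoint path, or [load_checkpoint()]
#'   result.
#' @param image grayscale matrix in `[0, 1]` (resized internally).
#' @return object of class `attention_stack`: list over depth of lists
#'   over heads of (N'+1) x (N'+1) row-stochastic matrices, with
#'   attributes `depth` and `heads` (rows of the panel = depth, columns =
#'   heads).
#' @export
extract_attention_maps <- function(model, image) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.list(model) && !inherits(model, "vit_model") && !is.null(model$model)) {
    model <- model$model
  }
  out <- vit_forward(model, list(image), training = FALSE, capture_attention = TRUE)
  maps <- lapply(out$attention, function(layer) layer[[1]])  # single image
  structure(maps, depth = length(maps), heads = length(maps[[1]]),
            class = "attention_stack")
}

#' @export
print.attention_stack <- function(x, ...) {
  cat(sprintf("attention stack: %d layers x %d heads, %d x %d maps\n",
              attr(x, "depth"), attr(x, "heads"),
              nrow(x[[1]][[1]]), ncol(x[[1]][[1]])))
  invisible(x)
}

#' Global attention feature map (GAFM)
#'
#' Implements the published definition exactly: the input slice is
#' resized to the model input resolution, every pixel is multiplied by
#' the sum over the final fully connected feature vector, and the result
#' is min-max normalized to integers in `[0, 255]` (half-up rounding).  A
#' constant map normalizes to all zeros with a warning.
#'
#' @param image grayscale matrix (raw slice, any size).
#' @param fc_vector final fully connected feature vector of the model for
#'   this slice (see [extract_fc_vector()]).
#' @param input_size model input side length the image is resized to.
#' @return object of class `gafm`: list with `image_resized`, `fc_vector`,
#'   `gafm` (real map) and `gafm_normalized` (integer map in 0..255).
#' @export
global_attention_feature_map <- function(image, fc_vector, input_size = 56L) {
  if (any(!is.finite(fc_vector))) stopf("global_attention_feature_map: non-finite fc_vector")
  img <- resize_bilinear(image, input_size, input_size)
  gafm <- img * sum(fc_vector)
  rng <- range(gafm)
  if (rng[1] == rng[2]) {
    warning("constant GAFM: normalized map defined as all zeros")
    norm <- matrix(0L, nrow(gafm), ncol(gafm))
  } else {
    norm <- round_half_up((gafm - rng[1]) * 255 / (rng[2] - rng[1]))
    storage.mode(norm) <- "integer"
  }
  structure(list(image_resized = img, fc_vector = fc_vector, gafm = gafm,
                 gafm_normalized = norm), class = "gafm")
}

#' Final fully connected feature vector for one slice
#'
#' Returns the normalized class-token embedding that feeds the linear
#' classifier - the model's final fully connected feature representation
#' used by the global attention map.
#'
#' @param model a `vit_model` or checkpoint.
#' @param image grayscale matrix in `[0, 1]`.
#' @return numeric vector of length `embed_dim`.
#' @export
extract_fc_vector <- function(model, image) {
  if (is.character(model)) model <- load_checkpoint(model)$model
  if (is.list(model) && !inherits(model, "vit_model") && !is.null(model$model)) {
    model <- model$model
  }
  as.numeric(vit_forward(model, list(image), training = FALSE)$fc_features)
}

# 0-255 min-max rendering of one map
render_map_255 <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(m), ncol(m)))
  round_half_up((m - rng[1]) * 255 / (rng[2] - rng[1]))
}

#' Write the depth x heads attention panel as one PNG
#'
#' Each map is min-max rendered to 8 bits; rows of the panel are layers
#' (depth), columns are heads, separated by 1-pixel gutters.
#'
#' @param stack an `attention_stack`.
#' @param path output PNG path.
#' @export
write_attention_panel <- function(stack, path) {
  depth <- attr(stack, "depth"); heads <- attr(stack, "heads")
  mh <- nrow(stack[[1]][[1]]); mw <- ncol(stack[[1]][[1]])
  panel <- matrix(255L, depth * (mh + 1) - 1, heads * (mw + 1) - 1)
  for (l in seq_len(depth)) {
    for (h in seq_len(heads)) {
      r0 <- (l - 1) * (mh + 1); c0 <- (h - 1) * (mw + 1)
      panel[r0 + seq_len(mh), c0 + seq_len(mw)] <- render_map_255(stack[[l]][[h]])
    }
  }
  png_write_gray(panel, path, 8)
}

#' Write a GAFM as a CIVIDIS-colored PNG
#'
#' @param gafm a `gafm` object.
#' @param path output PNG path.
#' @param colormap a `hcl.colors` palette name (default `"Cividis"`).
#' @export
write_gafm_png <- function(gafm, path, colormap = "Cividis") {
  pal <- grDevices::hcl.colors(256, colormap)
  rgb <- grDevices::col2rgb(pal)
  idx <- gafm$gafm_normalized + 1L
  h <- nrow(idx); w <- ncol(idx)
  arr <- array(0, c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, idx], h, w)
  png_write_rgb(arr, path)
}
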