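# Reverse-mode automatic differentiation on matrices.
#
# A small tape: every operation appends a node holding its value, parent
# nodes and a backward closure; ad_backward() walks the tape in reverse
# creation order (a valid topological order) accumulating gradients.
# Attention is a single composite node so the per-head work stays in
# tight BLAS calls.  All gradients are checked against central finite
# differences in the test suite.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$bw <- bw
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run backpropagation over a tape
#' @noRd
ad_backward <- function(tape, loss, seed_grad = 1) {
  loss$grad <- seed_grad
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad %*% t(nd$parents[[2]]$value))
    ad_accum(nd$parents[[2]], t(nd$parents[[1]]$value) %*% nd$grad)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad)
    ad_accum(nd$parents[[2]], nd$grad)
  })
}

# row-broadcast bias: a is n x d, b a length-d vector
ad_bias <- function(tape, a, b) {
  ad_node(tape, sweep(a$value, 2, b$value, `+`), list(a, b), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad)
    ad_accum(nd$parents[[2]], colSums(nd$grad))
  })
}

# column-broadcast gain: a n x d scaled per column by vector s (LayerScale)
ad_colscale <- function(tape, a, s) {
  ad_node(tape, sweep(a$value, 2, s$value, `*`), list(a, s), function(nd) {
    ad_accum(nd$parents[[1]], sweep(nd$grad, 2, nd$parents[[2]]$value, `*`))
    ad_accum(nd$parents[[2]], colSums(nd$grad * nd$parents[[1]]$value))
  })
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad * k)
  })
}

ad_gelu <- function(tape, a) {
  x <- a$value
  Phi <- stats::pnorm(x)
  ad_node(tape, x * Phi, list(a), function(nd) {
    xx <- nd$parents[[1]]$value
    ad_accum(nd$parents[[1]], nd$grad * (Phi + xx * stats::dnorm(xx)))
  })
}

ad_dropout <- function(tape, a, p, training) {
  if (!training || p <= 0) return(a)
  mask <- (stats::runif(length(a$value)) >= p) / (1 - p)
  dim(mask) <- dim(a$value)
  ad_node(tape, a$value * mask, list(a), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad * mask)
  })
}

# row-wise layer normalization with learnable gain/offset (length d)
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  val <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  ad_node(tape, val, list(x, gamma, beta), function(nd) {
    g <- nd$grad
    ad_accum(nd$parents[[2]], colSums(g * xhat))
    ad_accum(nd$parents[[3]], colSums(g))
    gxh <- sweep(g, 2, nd$parents[[2]]$value, `*`)
    gx <- inv * (gxh - rowMeans(gxh) - xhat * rowMeans(gxh * xhat))
    ad_accum(nd$parents[[1]], gx)
  })
}

# select rows (indices must be distinct)
ad_rows <- function(tape, x, idx) {
  ad_node(tape, x$value[idx, , drop = FALSE], list(x), function(nd) {
    gx <- matrix(0, nrow(nd$parents[[1]]$value), ncol(nd$parents[[1]]$value))
    gx[idx, ] <- nd$grad
    ad_accum(nd$parents[[1]], gx)
  })
}

# prepend a learnable class token (1 x d) to each image's token block
ad_prepend_cls <- function(tape, patches, cls, B, N) {
  d <- ncol(patches$value)
  Tt <- N + 1L
  cls_rows <- (seq_len(B) - 1L) * Tt + 1L
  patch_out <- setdiff(seq_len(B * Tt), cls_rows)
  val <- matrix(0, B * Tt, d)
  val[cls_rows, ] <- matrix(cls$value, B, d, byrow = TRUE)
  val[patch_out, ] <- patches$value
  ad_node(tape, val, list(patches, cls), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad[patch_out, , drop = FALSE])
    ad_accum(nd$parents[[2]], matrix(colSums(nd$grad[cls_rows, , drop = FALSE]), 1))
  })
}

# add a positional embedding (Tt x d) to every image block
ad_add_pos <- function(tape, x, pos, B, Tt) {
  grp <- rep(seq_len(Tt), B)
  ad_node(tape, x$value + pos$value[grp, , drop = FALSE], list(x, pos), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad)
    ad_accum(nd$parents[[2]], rowsum(nd$grad, grp))
  })
}

softmax_rows <- function(S) {
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S)
  E / rowSums(E)
}

#' Composite multi-head attention node
#'
#' Inputs `q` ((B*Tq) x H*dh), `k`, `v` ((B*Tk) x H*dh) are already
#' projected.  `variant` selects the map algebra:
#' \itemize{
#'   \item `softmax`: standard scaled dot-product per head;
#'   \item `reattention`: post-softmax maps mixed across heads by a
#'     learnable H x H matrix, renormalized by a LayerNorm over the head
#'     axis (DeepViT);
#'   \item `talking`: learnable H x H mixes before and after the softmax
#'     (CaIT).
#' }
#' `extra` carries the mixing-parameter nodes.  When `store` is an
#' environment, the per-image post-softmax maps are saved in
#' `store$maps[[image]][[head]]`.
#' @noRd
ad_attend <- function(tape, q, k, v, B, H, Tq, Tk, dh,
                      variant = "softmax", extra = list(), store = NULL) {
  scale <- 1 / sqrt(dh)
  hcols <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  qrows <- function(b) ((b - 1L) * Tq + 1L):(b * Tq)
  krows <- function(b) ((b - 1L) * Tk + 1L):(b * Tk)
  cache <- vector("list", B)
  out <- matrix(0, B * Tq, H * dh)
  ln_eps <- 1e-5

  for (b in seq_len(B)) {
    Qb <- q$value[qrows(b), , drop = FALSE]
    Kb <- k$value[krows(b), , drop = FALSE]
    Vb <- v$value[krows(b), , drop = FALSE]
    cb <- list(A = vector("list", H))
    if (variant == "softmax") {
      for (h in seq_len(H)) {
        S <- (Qb[, hcols[[h]], drop = FALSE] %*% t(Kb[, hcols[[h]], drop = FALSE])) * scale
        A <- softmax_rows(S)
        cb$A[[h]] <- A
        out[qrows(b), hcols[[h]]] <- A %*% Vb[, hcols[[h]], drop = FALSE]
      }
    } else if (variant == "reattention") {
      theta <- extra$theta$value
      lng <- extra$ln_gamma$value; lnb <- extra$ln_beta$value
      Smat <- matrix(0, Tq * Tk, H)
      for (h in seq_len(H)) {
        S <- (Qb[, hcols[[h]], drop = FALSE] %*% t(Kb[, hcols[[h]], drop = FALSE])) * scale
        A <- softmax_rows(S)
        cb$A[[h]] <- A
        Smat[, h] <- as.vector(A)
      }
      R1 <- Smat %*% t(theta)
      mu <- rowMeans(R1); rc <- R1 - mu
      vv <- rowMeans(rc * rc); inv <- 1 / sqrt(vv + ln_eps)
      rhat <- rc * inv
      R2 <- sweep(sweep(rhat, 2, lng, `*`), 2, lnb, `+`)
      for (h in seq_len(H)) {
        out[qrows(b), hcols[[h]]] <-
          matrix(R2[, h], Tq, Tk) %*% Vb[, hcols[[h]], drop = FALSE]
      }
      cb$Smat <- Smat; cb$rhat <- rhat; cb$inv <- inv; cb$R2 <- R2
    } else if (variant == "talking") {
      mp <- extra$mix_pre$value; mq <- extra$mix_post$value
      S0 <- matrix(0, Tq * Tk, H)
      for (h in seq_len(H)) {
        S0[, h] <- as.vector((Qb[, hcols[[h]], drop = FALSE] %*%
                                t(Kb[, hcols[[h]], drop = FALSE])) * scale)
      }
      S1 <- S0 %*% t(mp)
      Amat <- matrix(0, Tq * Tk, H)
      for (h in seq_len(H)) {
        A <- softmax_rows(matrix(S1[, h], Tq, Tk))
        cb$A[[h]] <- A
        Amat[, h] <- as.vector(A)
      }
      A2 <- Amat %*% t(mq)
      for (h in seq_len(H)) {
        out[qrows(b), hcols[[h]]] <-
          matrix(A2[, h], Tq, Tk) %*% Vb[, hcols[[h]], drop = FALSE]
      }
      cb$S0 <- S0; cb$Amat <- Amat; cb$A2 <- A2
    } else stopf("ad_attend: unknown variant %s", variant)
    cache[[b]] <- cb
  }
  if (!is.null(store)) store$maps <- lapply(cache, `[[`, "A")

  parents <- c(list(q, k, v), extra)
  ad_node(tape, out, parents, function(nd) {
    g <- nd$grad
    gq <- matrix(0, nrow(q$value), ncol(q$value))
    gk <- matrix(0, nrow(k$value), ncol(k$value))
    gv <- matrix(0, nrow(v$value), ncol(v$value))
    if (variant == "reattention") {
      gtheta <- matrix(0, H, H); glng <- numeric(H); glnb <- numeric(H)
    }
    if (variant == "talking") {
      gmp <- matrix(0, H, H); gmq <- matrix(0, H, H)
    }
    for (b in seq_len(B)) {
      Qb <- q$value[qrows(b), , drop = FALSE]
      Kb <- k$value[krows(b), , drop = FALSE]
      Vb <- v$value[krows(b), , drop = FALSE]
      cb <- cache[[b]]
      gOb <- g[qrows(b), , drop = FALSE]
      if (variant == "softmax") {
        for (h in seq_len(H)) {
          A <- cb$A[[h]]
          gOh <- gOb[, hcols[[h]], drop = FALSE]
          gA <- gOh %*% t(Vb[, hcols[[h]], drop = FALSE])
          gv[krows(b), hcols[[h]]] <- gv[krows(b), hcols[[h]]] + t(A) %*% gOh
          gS <- (gA - rowSums(gA * A)) * A
          gq[qrows(b), hcols[[h]]] <- gq[qrows(b), hcols[[h]]] +
            gS %*% Kb[, hcols[[h]], drop = FALSE] * scale
          gk[krows(b), hcols[[h]]] <- gk[krows(b), hcols[[h]]] +
            t(gS) %*% Qb[, hcols[[h]], drop = FALSE] * scale
        }
      } else if (variant == "reattention") {
        theta <- extra$theta$value; lng <- extra$ln_gamma$value
        gR2 <- matrix(0, Tq * Tk, H)
        for (h in seq_len(H)) {
          gOh <- gOb[, hcols[[h]], drop = FALSE]
          gR2[, h] <- as.vector(gOh %*% t(Vb[, hcols[[h]], drop = FALSE]))
          gv[krows(b), hcols[[h]]] <- gv[krows(b), hcols[[h]]] +
            t(matrix(cb$R2[, h], Tq, Tk)) %*% gOh
        }
        glng <- glng + colSums(gR2 * cb$rhat)
        glnb <- glnb + colSums(gR2)
        gxh <- sweep(gR2, 2, lng, `*`)
        gR1 <- cb$inv * (gxh - rowMeans(gxh) - cb$rhat * rowMeans(gxh * cb$rhat))
        gS <- gR1 %*% theta
        gtheta <- gtheta + t(gR1) %*% cb$Smat
        for (h in seq_len(H)) {
          A <- cb$A[[h]]
          gA <- matrix(gS[, h], Tq, Tk)
          gSh <- (gA - rowSums(gA * A)) * A
          gq[qrows(b), hcols[[h]]] <- gq[qrows(b), hcols[[h]]] +
            gSh %*% Kb[, hcols[[h]], drop = FALSE] * scale
          gk[krows(b), hcols[[h]]] <- gk[krows(b), hcols[[h]]] +
            t(gSh) %*% Qb[, hcols[[h]], drop = FALSE] * scale
        }
      } else {                           # talking
        mp <- extra$mix_pre$value; mq <- extra$mix_post$value
        gA2 <- matrix(0, Tq * Tk, H)
        for (h in seq_len(H)) {
          gOh <- gOb[, hcols[[h]], drop = FALSE]
          gA2[, h] <- as.vector(gOh %*% t(Vb[, hcols[[h]], drop = FALSE]))
          gv[krows(b), hcols[[h]]] <- gv[krows(b), hcols[[h]]] +
            t(matrix(cb$A2[, h], Tq, Tk)) %*% gOh
        }
        gAmat <- gA2 %*% mq
        gmq <- gmq + t(gA2) %*% cb$Amat
        gS1 <- matrix(0, Tq * Tk, H)
        for (h in seq_len(H)) {
          A <- cb$A[[h]]
          gA <- matrix(gAmat[, h], Tq, Tk)
          gS1[, h] <- as.vector((gA - rowSums(gA * A)) * A)
        }
        gS0 <- gS1 %*% mp
        gmp <- gmp + t(gS1) %*% cb$S0
        for (h in seq_len(H)) {
          gSh <- matrix(gS0[, h], Tq, Tk)
          gq[qrows(b), hcols[[h]]] <- gq[qrows(b), hcols[[h]]] +
            gSh %*% Kb[, hcols[[h]], drop = FALSE] * scale
          gk[krows(b), hcols[[h]]] <- gk[krows(b), hcols[[h]]] +
            t(gSh) %*% Qb[, hcols[[h]], drop = FALSE] * scale
        }
      }
    }
    ad_accum(nd$parents[[1]], gq)
    ad_accum(nd$parents[[2]], gk)
    ad_accum(nd$parents[[3]], gv)
    if (variant == "reattention") {
      ad_accum(extra$theta, gtheta)
      ad_accum(extra$ln_gamma, glng)
      ad_accum(extra$ln_beta, glnb)
    }
    if (variant == "talking") {
      ad_accum(extra$mix_pre, gmp)
      ad_accum(extra$mix_post, gmq)
    }
  })
}

# mean cross-entropy over a batch; labels are 1-based integers
ad_softmax_crossentropy <- function(tape, logits, labels) {
  P <- softmax_rows(logits$value)
  n <- nrow(P)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), labels)], 1e-300)))
  ad_node(tape, loss, list(logits), function(nd) {
    Y <- matrix(0, n, ncol(P))
    Y[cbind(seq_len(n), labels)] <- 1
    ad_accum(nd$parents[[1]], nd$grad * (P - Y) / n)
  })
}
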