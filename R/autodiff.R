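# Minimal tape-based reverse-mode automatic differentiation over numeric
# arrays. A forward pass records one node per operation on a package-level
# tape; ad_backward() replays the tape in reverse, accumulating gradients
# into every tensor whose `track` flag is set. Tensors are environments so
# gradients accumulate in place across fan-out.
#
# The engine exists because the trainable network needs end-to-end
# gradients (including through bilinear sampling coordinates) and no
# deep-learning framework is part of the package's dependency set.

.ad <- new.env(parent = emptyenv())
.ad$tape <- list()
.ad$n <- 0L

#' Start recording a fresh autodiff tape
#'
#' Clears the operation tape. Call once before each forward pass whose
#' gradients are needed.
#' @return Invisibly, `NULL`.
#' @keywords internal
ad_begin <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  invisible(NULL)
}

ad_push <- function(out, bw) {
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) length(.ad$tape) <- 2L * length(.ad$tape)
  .ad$tape[[n]] <- list(out = out, bw = bw)
  .ad$n <- n
  out
}

#' Create an autodiff tensor
#' @param val numeric array/matrix/vector.
#' @param track logical; accumulate a gradient for this tensor?
#' @keywords internal
ad_tensor <- function(val, track = TRUE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$track <- track
  class(e) <- "adtensor"
  e
}

is_ad <- function(x) inherits(x, "adtensor")
ad_val <- function(x) if (is_ad(x)) x$val else x

ad_accum <- function(t, g) {
  if (is_ad(t) && isTRUE(t$track)) {
    t$grad <- if (is.null(t$grad)) g else t$grad + g
  }
  invisible(NULL)
}

#' Run backpropagation from a scalar loss tensor
#' @param loss scalar `adtensor` produced under the current tape.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$val) == 1L)
  loss$grad <- 1
  for (i in seq(.ad$n, 1L)) {
    node <- .ad$tape[[i]]
    g <- node$out$grad
    if (!is.null(g)) node$bw(g)
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- elementwise and linear-algebra ops -------------------------------------

ad_add <- function(a, b) {
  out <- ad_tensor(ad_val(a) + ad_val(b))
  ad_push(out, function(g) { ad_accum(a, g); ad_accum(b, g) })
}

ad_scale <- function(a, s) {
  out <- ad_tensor(ad_val(a) * s)
  ad_push(out, function(g) ad_accum(a, g * s))
}

ad_relu <- function(x) {
  v <- ad_val(x)
  out <- ad_tensor(pmax(v, 0))
  keep <- v > 0
  ad_push(out, function(g) ad_accum(x, g * keep))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-ad_val(x)))
  out <- ad_tensor(s)
  ad_push(out, function(g) ad_accum(x, g * s * (1 - s)))
}

# X: N x R, W: R x C
ad_matmul <- function(X, W) {
  xv <- ad_val(X); wv <- ad_val(W)
  out <- ad_tensor(xv %*% wv)
  ad_push(out, function(g) {
    ad_accum(X, g %*% t(wv))
    ad_accum(W, t(xv) %*% g)
  })
}

# add a length-C bias to every row of an N x C matrix
ad_add_rowvec <- function(X, b) {
  bv <- ad_val(b)
  out <- ad_tensor(sweep(ad_val(X), 2L, bv, "+"))
  ad_push(out, function(g) {
    ad_accum(X, g)
    ad_accum(b, colSums(g))
  })
}

# add a P x C matrix to tokens stored part-fastest: row p + P*(cell-1)
ad_add_tokenwise <- function(X, E) {
  ev <- ad_val(E)
  P <- nrow(ev)
  xv <- ad_val(X)
  n_rep <- nrow(xv) / P
  big <- ev[rep(seq_len(P), n_rep), , drop = FALSE]
  out <- ad_tensor(xv + big)
  ad_push(out, function(g) {
    ad_accum(X, g)
    if (is_ad(E) && isTRUE(E$track)) {
      ge <- matrix(0, P, ncol(ev))
      for (p in seq_len(P)) {
        ge[p, ] <- colSums(g[seq(p, nrow(g), by = P), , drop = FALSE])
      }
      ad_accum(E, ge)
    }
  })
}

ad_rows <- function(X, idx) {
  xv <- ad_val(X)
  uniq <- !anyDuplicated(idx)
  out <- ad_tensor(xv[idx, , drop = FALSE])
  ad_push(out, function(g) {
    if (is_ad(X) && isTRUE(X$track)) {
      gx <- matrix(0, nrow(xv), ncol(xv))
      if (uniq) {
        gx[idx, ] <- g
      } else {
        for (k in seq_along(idx)) gx[idx[k], ] <- gx[idx[k], ] + g[k, ]
      }
      ad_accum(X, gx)
    }
  })
}

ad_cols <- function(X, idx) {
  xv <- ad_val(X)
  uniq <- !anyDuplicated(idx)
  out <- ad_tensor(xv[, idx, drop = FALSE])
  ad_push(out, function(g) {
    if (is_ad(X) && isTRUE(X$track)) {
      gx <- matrix(0, nrow(xv), ncol(xv))
      if (uniq) {
        gx[, idx] <- g
      } else {
        for (k in seq_along(idx)) gx[, idx[k]] <- gx[, idx[k]] + g[, k]
      }
      ad_accum(X, gx)
    }
  })
}

ad_cbind <- function(xs) {
  vals <- lapply(xs, ad_val)
  widths <- vapply(vals, ncol, 1L)
  out <- ad_tensor(do.call(cbind, vals))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_push(out, function(g) {
    for (k in seq_along(xs)) {
      ad_accum(xs[[k]], g[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

ad_reshape <- function(x, dims) {
  xv <- ad_val(x)
  out <- ad_tensor(array(xv, dim = dims))
  old <- dim(xv)
  ad_push(out, function(g) {
    gr <- if (is.null(old)) as.vector(g) else array(g, dim = old)
    ad_accum(x, gr)
  })
}

# --- normalisation ----------------------------------------------------------

# row-wise layer normalisation of an N x C matrix
ad_layernorm <- function(X, gamma, beta, eps = 1e-5) {
  xv <- ad_val(X)
  C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  varr <- rowMeans(xc^2)
  istd <- 1 / sqrt(varr + eps)
  xhat <- xc * istd
  gv <- ad_val(gamma); bv <- ad_val(beta)
  out <- ad_tensor(sweep(xhat, 2L, gv, "*") + matrix(bv, nrow(xv), C, byrow = TRUE))
  ad_push(out, function(g) {
    ad_accum(gamma, colSums(g * xhat))
    ad_accum(beta, colSums(g))
    if (is_ad(X) && isTRUE(X$track)) {
      gh <- sweep(g, 2L, gv, "*")
      gx <- istd * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat))
      ad_accum(X, gx)
    }
  })
}

# per-channel normalisation of an H x W x C feature map over its spatial
# extent (single-image batch statistics, used identically in train and eval
# so both modes stay deterministic and bit-equal)
ad_bn2d <- function(X, gamma, beta, eps = 1e-5) {
  xv <- ad_val(X)
  d <- dim(xv)
  M <- d[1] * d[2]
  xm <- matrix(xv, M, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  varr <- colMeans(xc^2)
  istd <- 1 / sqrt(varr + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  gv <- ad_val(gamma); bv <- ad_val(beta)
  outm <- sweep(xhat, 2L, gv, "*")
  outm <- sweep(outm, 2L, bv, "+")
  out <- ad_tensor(array(outm, dim = d))
  ad_push(out, function(g) {
    gm <- matrix(g, M, d[3])
    ad_accum(gamma, colSums(gm * xhat))
    ad_accum(beta, colSums(gm))
    if (is_ad(X) && isTRUE(X$track)) {
      gh <- sweep(gm, 2L, gv, "*")
      t1 <- sweep(gh, 2L, colMeans(gh))
      t2 <- sweep(xhat, 2L, colMeans(gh * xhat), "*")
      gx <- sweep(t1 - t2, 2L, istd, "*")
      ad_accum(X, array(gx, dim = d))
    }
  })
}

# --- convolution and sampling (compiled kernels) ----------------------------

# x: H x W x Cin tensor; w: kh x kw x Cin x Cout param; b: length-Cout param
ad_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  xv <- ad_val(x); wv <- ad_val(w)
  dw <- dim(wv); dx <- dim(xv)
  fw <- cpp_conv2d_fw(xv, as.vector(wv), ad_val(b),
                      dw[1], dw[2], dw[4], stride, pad)
  out <- ad_tensor(fw$out)
  col <- fw$col
  need_gx <- is_ad(x) && isTRUE(x$track)
  ad_push(out, function(g) {
    gr <- cpp_conv2d_bw(col, as.vector(wv), g, dx[1], dx[2], dx[3],
                        dw[1], dw[2], dw[4], stride, pad, need_gx)
    if (need_gx) ad_accum(x, gr$gx)
    ad_accum(w, array(gr$gw, dim = dw))
    ad_accum(b, as.vector(gr$gb))
  })
}

# f: H x W x C tensor; xs, ys: length-N coordinate tensors (0-based pixels
# of f's grid). Returns N x C. Gradients flow to f and to the coordinates.
ad_grid_sample <- function(f, xs, ys) {
  fv <- ad_val(f); xv <- ad_val(xs); yv <- ad_val(ys)
  out <- ad_tensor(cpp_grid_sample_fw(fv, xv, yv))
  ad_push(out, function(g) {
    gr <- cpp_grid_sample_bw(fv, xv, yv, g)
    ad_accum(f, gr$gf)
    gx <- as.vector(gr$gx); gy <- as.vector(gr$gy)
    if (!is.null(dim(xv))) dim(gx) <- dim(xv)
    if (!is.null(dim(yv))) dim(gy) <- dim(yv)
    ad_accum(xs, gx)
    ad_accum(ys, gy)
  })
}

# --- attention and fusion composites ----------------------------------------

# Scaled dot-product attention across the P tokens of every spatial cell.
# Q, K, V: (N*P) x D matrices with part index fastest (row p + P*(cell-1)).
# Cells never interact. Attention weights are stashed on the output tensor
# (attr "attn") for inspection.
ad_attention <- function(Q, K, V, P, scale) {
  qv <- ad_val(Q); kv <- ad_val(K); vv <- ad_val(V)
  NP <- nrow(qv); D <- ncol(qv); N <- NP %/% P
  ridx <- lapply(seq_len(P), function(p) seq(p, NP, by = P))
  Qs <- lapply(ridx, function(ix) qv[ix, , drop = FALSE])
  Ks <- lapply(ridx, function(ix) kv[ix, , drop = FALSE])
  Vs <- lapply(ridx, function(ix) vv[ix, , drop = FALSE])
  S <- array(0, dim = c(N, P, P))
  for (i in seq_len(P)) for (j in seq_len(P)) {
    S[, i, j] <- rowSums(Qs[[i]] * Ks[[j]]) * scale
  }
  A <- array(0, dim = c(N, P, P))
  for (i in seq_len(P)) {
    Si <- S[, i, ]; dim(Si) <- c(N, P)
    m <- Si[, 1]
    if (P > 1L) for (j in 2:P) m <- pmax(m, Si[, j])
    e <- exp(Si - m)
    A[, i, ] <- e / rowSums(e)
  }
  O <- matrix(0, NP, D)
  for (i in seq_len(P)) {
    acc <- A[, i, 1] * Vs[[1]]
    if (P > 1L) for (j in 2:P) acc <- acc + A[, i, j] * Vs[[j]]
    O[ridx[[i]], ] <- acc
  }
  out <- ad_tensor(O)
  attr(out, "attn") <- A
  ad_push(out, function(g) {
    gs_list <- lapply(ridx, function(ix) g[ix, , drop = FALSE])
    gA <- array(0, dim = c(N, P, P))
    gV <- matrix(0, NP, D)
    for (j in seq_len(P)) {
      gVj <- A[, 1, j] * gs_list[[1]]
      gA[, 1, j] <- rowSums(gs_list[[1]] * Vs[[j]])
      if (P > 1L) for (i in 2:P) {
        gVj <- gVj + A[, i, j] * gs_list[[i]]
        gA[, i, j] <- rowSums(gs_list[[i]] * Vs[[j]])
      }
      gV[ridx[[j]], ] <- gVj
    }
    ad_accum(V, gV)
    # softmax backward per (cell, i) row, then scale
    gS <- array(0, dim = c(N, P, P))
    for (i in seq_len(P)) {
      Ai <- A[, i, ]; dim(Ai) <- c(N, P)
      gAi <- gA[, i, ]; dim(gAi) <- c(N, P)
      dot <- rowSums(gAi * Ai)
      gS[, i, ] <- Ai * (gAi - dot) * scale
    }
    gQ <- matrix(0, NP, D); gK <- matrix(0, NP, D)
    for (i in seq_len(P)) {
      accQ <- gS[, i, 1] * Ks[[1]]
      if (P > 1L) for (j in 2:P) accQ <- accQ + gS[, i, j] * Ks[[j]]
      gQ[ridx[[i]], ] <- accQ
    }
    for (j in seq_len(P)) {
      accK <- gS[, 1, j] * Qs[[1]]
      if (P > 1L) for (i in 2:P) accK <- accK + gS[, i, j] * Qs[[i]]
      gK[ridx[[j]], ] <- accK
    }
    ad_accum(Q, gQ)
    ad_accum(K, gK)
  })
}

# Adaptive additive fusion: out = sum_l softmax(theta)_l * x_l, where the
# x_l are same-shaped matrices and theta is a length-L logit tensor.
ad_fuse_add <- function(xs, theta) {
  tv <- as.vector(ad_val(theta))
  a <- exp(tv - max(tv)); a <- a / sum(a)
  vals <- lapply(xs, ad_val)
  acc <- a[1] * vals[[1]]
  if (length(xs) > 1L) for (l in 2:length(xs)) acc <- acc + a[l] * vals[[l]]
  out <- ad_tensor(acc)
  attr(out, "fuse_weights") <- a
  ad_push(out, function(g) {
    ga <- numeric(length(xs))
    for (l in seq_along(xs)) {
      ad_accum(xs[[l]], a[l] * g)
      ga[l] <- sum(g * vals[[l]])
    }
    if (is_ad(theta) && isTRUE(theta$track)) {
      ad_accum(theta, a * (ga - sum(ga * a)))
    }
  })
}

# --- scalar losses ----------------------------------------------------------

# shared numeric core of the penalty-reduced focal loss (natural log,
# predictions clamped to [eps, 1-eps]); returns loss and d(loss)/d(pred)
focal_core <- function(pred, target, n_pos, alpha, beta, eps = 1e-6) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  pos <- target >= 1
  lp <- (1 - p)^alpha * log(p)
  ln <- (1 - target)^beta * p^alpha * log(1 - p)
  loss <- -(sum(lp[pos]) + sum(ln[!pos])) / n_pos
  dpos <- -alpha * (1 - p)^(alpha - 1) * log(p) + (1 - p)^alpha / p
  dneg <- (1 - target)^beta * (alpha * p^(alpha - 1) * log(1 - p) - p^alpha / (1 - p))
  d <- ifelse(pos, dpos, dneg)
  d[pred < eps | pred > 1 - eps] <- 0
  list(loss = loss, grad = -d / n_pos)
}

ad_focal <- function(pred, target, n_pos, alpha = 2, beta = 4, eps = 1e-6) {
  fc <- focal_core(ad_val(pred), target, n_pos, alpha, beta, eps)
  out <- ad_tensor(fc$loss)
  ad_push(out, function(g) ad_accum(pred, g * fc$grad))
}

ad_l1_masked <- function(pred, target, mask, denom) {
  pv <- ad_val(pred)
  diff <- (pv - target) * mask
  out <- ad_tensor(sum(abs(diff)) / denom)
  ad_push(out, function(g) ad_accum(pred, g * sign(diff) * mask / denom))
}

ad_wsum <- function(xs, weights) {
  tot <- 0
  for (k in seq_along(xs)) tot <- tot + weights[k] * ad_val(xs[[k]])
  out <- ad_tensor(tot)
  ad_push(out, function(g) {
    for (k in seq_along(xs)) ad_accum(xs[[k]], g * weights[k])
  })
}
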