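# Central-difference checks of the reverse-mode engine: every kernel used
# by the network must agree with numeric gradients.

sp <- asNamespace("structpose")

scalar_loss <- function(out) {
  l <- sp$ad_tensor(sum(sp$ad_val(out)^2) / 2)
  sp$ad_push(l, function(g) sp$ad_accum(out, g * sp$ad_val(out)))
  l
}

test_that("convolution gradients match central differences", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3)
  run <- function(xx, ww, bb) {
    sp$ad_begin()
    xt <- sp$ad_tensor(xx); wt <- sp$ad_tensor(ww); bt <- sp$ad_tensor(bb)
    l <- scalar_loss(sp$ad_conv2d(xt, wt, bt, 2L, 1L))
    sp$ad_backward(l)
    list(l = sp$ad_val(l), gx = xt$grad, gw = wt$grad, gb = bt$grad)
  }
  r <- run(x, w, b)
  expect_lt(max(abs(r$gx - num_grad(function(z) run(z, w, b)$l, x))), 1e-6)
  expect_lt(max(abs(r$gw - num_grad(function(z) run(x, z, b)$l, w))), 1e-6)
  expect_lt(max(abs(r$gb - num_grad(function(z) run(x, w, z)$l, b))), 1e-6)
})

test_that("bilinear sampling gradients flow to features and coordinates", {
  set.seed(2)
  f <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  xs <- runif(4, 0.3, 3.6); ys <- runif(4, 0.3, 3.6)
  run <- function(ff, xx, yy) {
    sp$ad_begin()
    ft <- sp$ad_tensor(ff); xt <- sp$ad_tensor(xx); yt <- sp$ad_tensor(yy)
    l <- scalar_loss(sp$ad_grid_sample(ft, xt, yt))
    sp$ad_backward(l)
    list(l = sp$ad_val(l), gf = ft$grad, gx = xt$grad, gy = yt$grad)
  }
  r <- run(f, xs, ys)
  expect_lt(max(abs(r$gf - num_grad(function(z) run(z, xs, ys)$l, f))), 1e-6)
  expect_lt(max(abs(r$gx - num_grad(function(z) run(f, z, ys)$l, xs))), 1e-6)
  expect_lt(max(abs(r$gy - num_grad(function(z) run(f, xs, z)$l, ys))), 1e-6)
})

test_that("normalisation and attention composites match central differences", {
  set.seed(3)
  X <- matrix(rnorm(12 * 6), 12, 6)   # 4 cells x 3 parts, width 6
  g1 <- runif(6, 0.5, 1.5); b1 <- rnorm(6)
  run_ln <- function(xx) {
    sp$ad_begin()
    xt <- sp$ad_tensor(xx)
    l <- scalar_loss(sp$ad_layernorm(xt, sp$ad_tensor(g1), sp$ad_tensor(b1)))
    sp$ad_backward(l); list(l = sp$ad_val(l), gx = xt$grad)
  }
  r <- run_ln(X)
  expect_lt(max(abs(r$gx - num_grad(function(z) run_ln(z)$l, X))), 1e-5)

  run_att <- function(qq, kk, vv) {
    sp$ad_begin()
    qt <- sp$ad_tensor(qq); kt <- sp$ad_tensor(kk); vt <- sp$ad_tensor(vv)
    l <- scalar_loss(sp$ad_attention(qt, kt, vt, 3L, 1 / sqrt(6)))
    sp$ad_backward(l)
    list(l = sp$ad_val(l), gq = qt$grad, gk = kt$grad, gv = vt$grad)
  }
  Q <- matrix(rnorm(12 * 6), 12, 6); K <- matrix(rnorm(12 * 6), 12, 6)
  V <- matrix(rnorm(12 * 6), 12, 6)
  r <- run_att(Q, K, V)
  expect_lt(max(abs(r$gq - num_grad(function(z) run_att(z, K, V)$l, Q))), 1e-5)
  expect_lt(max(abs(r$gk - num_grad(function(z) run_att(Q, z, V)$l, K))), 1e-5)
  expect_lt(max(abs(r$gv - num_grad(function(z) run_att(Q, K, z)$l, V))), 1e-5)

  run_bn <- function(xx) {
    sp$ad_begin()
    xt <- sp$ad_tensor(xx)
    l <- scalar_loss(sp$ad_bn2d(xt, sp$ad_tensor(g1[1:3]), sp$ad_tensor(b1[1:3])))
    sp$ad_backward(l); list(l = sp$ad_val(l), gx = xt$grad)
  }
  Xb <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  r <- run_bn(Xb)
  expect_lt(max(abs(r$gx - num_grad(function(z) run_bn(z)$l, Xb))), 1e-5)
})

test_that("focal and masked-L1 loss gradients match central differences", {
  set.seed(4)
  target <- matrix(0, 4, 4); target[2, 2] <- 1; target[1, 1] <- 0.4
  pred <- matrix(runif(16, 0.05, 0.95), 4, 4)
  run_f <- function(pp) {
    sp$ad_begin()
    pt <- sp$ad_tensor(pp)
    l <- sp$ad_focal(pt, target, 1, 2, 4)
    sp$ad_backward(l); list(l = sp$ad_val(l), g = pt$grad)
  }
  r <- run_f(pred)
  expect_lt(max(abs(r$g - num_grad(function(z) run_f(z)$l, pred))), 1e-5)

  tg <- matrix(rnorm(6), 2, 3); mask <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3)
  pr <- matrix(rnorm(6), 2, 3)
  run_l1 <- function(pp) {
    sp$ad_begin()
    pt <- sp$ad_tensor(pp)
    l <- sp$ad_l1_masked(pt, tg, mask, 4)
    sp$ad_backward(l); list(l = sp$ad_val(l), g = pt$grad)
  }
  r <- run_l1(pr)
  expect_lt(max(abs(r$g - num_grad(function(z) run_l1(z)$l, pr))), 1e-6)
})

test_that("fusion weights are softmax-normalized and differentiable", {
  set.seed(5)
  xs <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2))
  th <- c(0.3, -0.7)
  run <- function(tt) {
    sp$ad_begin()
    tht <- sp$ad_tensor(tt)
    l <- scalar_loss(sp$ad_fuse_add(lapply(xs, sp$ad_tensor), tht))
    sp$ad_backward(l); list(l = sp$ad_val(l), g = tht$grad)
  }
  r <- run(th)
  expect_lt(max(abs(r$g - num_grad(function(z) run(z)$l, th))), 1e-6)
  sp$ad_begin()
  o <- sp$ad_fuse_add(lapply(xs, sp$ad_tensor), sp$ad_tensor(th))
  expect_equal(sum(attr(o, "fuse_weights")), 1)
})
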