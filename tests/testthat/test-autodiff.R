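# The reverse-mode tape must agree with central finite differences for every
# operator the networks use, and must accumulate gradients over shared nodes.

test_that("convolution gradients match finite differences (strides, paddings)", {
  set.seed(11)
  for (case in list(list(stride = 1L, pad = 1L, mode = "zero"),
                    list(stride = 2L, pad = 1L, mode = "zero"),
                    list(stride = 1L, pad = 2L, mode = "reflect"))) {
    x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
    b <- rnorm(2)
    xn <- ns$ad_tensor(x, requires_grad = TRUE)
    wn <- ns$ad_tensor(w, requires_grad = TRUE)
    bn <- ns$ad_tensor(b, requires_grad = TRUE)
    y <- ns$ad_conv2d(xn, wn, bn, stride = case$stride, pad = case$pad,
                      pad_mode = case$mode)
    loss <- ns$ad_mean(ns$ad_mul(y, y))
    ns$ad_backward(loss)
    pm <- if (case$mode == "reflect") 1L else 0L
    f <- function(v, what) {
      xs <- x; ws <- w; bs <- b
      if (what == "x") xs <- array(v, dim(x))
      if (what == "w") ws <- array(v, dim(w))
      if (what == "b") bs <- v
      mean(ns$cpp_conv2d_fw(xs, ws, bs, case$stride, case$pad, pm)^2)
    }
    expect_lt(max(abs(xn$grad - num_grad(function(v) f(v, "x"), x))), 1e-6)
    expect_lt(max(abs(wn$grad - num_grad(function(v) f(v, "w"), w))), 1e-6)
    expect_lt(max(abs(bn$grad - num_grad(function(v) f(v, "b"), b))), 1e-6)
  }
})

test_that("grid sampling gradients match finite differences", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  grid <- identityGrid(6, 6) + array(rnorm(72, sd = 0.07), c(6, 6, 2))
  for (padding in c("border", "zeros")) {
    xn <- ns$ad_tensor(x, requires_grad = TRUE)
    gn <- ns$ad_tensor(grid, requires_grad = TRUE)
    y <- ns$ad_grid_sample(xn, gn, padding)
    ns$ad_backward(ns$ad_sum(ns$ad_mul(y, y)))
    pm <- if (padding == "border") 1L else 0L
    fx <- function(v) sum(ns$cpp_grid_sample_fw(array(v, dim(x)), grid, pm)^2)
    fg <- function(v) sum(ns$cpp_grid_sample_fw(x, array(v, dim(grid)), pm)^2)
    expect_lt(max(abs(xn$grad - num_grad(fx, x))), 1e-6)
    expect_lt(max(abs(gn$grad - num_grad(fg, grid))), 1e-6)
  }
})

test_that("instance norm, upsampling, pooling and linear layers differentiate correctly", {
  set.seed(13)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  wt <- array(rnorm(48), c(4, 4, 3))
  xn <- ns$ad_tensor(x, requires_grad = TRUE)
  ns$ad_backward(ns$ad_sum(ns$ad_mul(ns$ad_instance_norm(xn), ns$ad_tensor(wt))))
  fin <- function(v) {
    a <- array(v, c(4, 4, 3)); mu <- apply(a, 3, mean)
    ac <- sweep(a, 3, mu); s <- sqrt(apply(ac^2, 3, mean) + 1e-5)
    sum(sweep(ac, 3, s, "/") * wt)
  }
  expect_lt(max(abs(xn$grad - num_grad(fin, x))), 1e-6)

  wt2 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  xn2 <- ns$ad_tensor(x, requires_grad = TRUE)
  ns$ad_backward(ns$ad_sum(ns$ad_mul(ns$ad_upsample2(xn2), ns$ad_tensor(wt2))))
  fup <- function(v) {
    a <- array(v, c(4, 4, 3))
    sum(a[rep(1:4, each = 2), rep(1:4, each = 2), ] * wt2)
  }
  expect_lt(max(abs(xn2$grad - num_grad(fup, x))), 1e-6)

  xn3 <- ns$ad_tensor(x, requires_grad = TRUE)
  cw <- rnorm(3)
  ns$ad_backward(ns$ad_sum(ns$ad_mul(ns$ad_gap(xn3), ns$ad_tensor(cw))))
  fgap <- function(v) sum(apply(array(v, c(4, 4, 3)), 3, mean) * cw)
  expect_lt(max(abs(xn3$grad - num_grad(fgap, x))), 1e-6)

  W <- matrix(rnorm(12), 3, 4); b <- rnorm(3); v <- rnorm(4)
  vn <- ns$ad_tensor(v, requires_grad = TRUE)
  Wn <- ns$ad_tensor(W, requires_grad = TRUE)
  bn <- ns$ad_tensor(b, requires_grad = TRUE)
  ns$ad_backward(ns$ad_sum(ns$ad_linear(vn, Wn, bn)))
  expect_equal(vn$grad, as.vector(t(W) %*% rep(1, 3)), tolerance = 1e-12)
  expect_equal(Wn$grad, outer(rep(1, 3), v), tolerance = 1e-12)
  expect_equal(bn$grad, rep(1, 3), tolerance = 1e-12)
})

test_that("gradients accumulate over nodes used multiple times", {
  x <- ns$ad_tensor(2, requires_grad = TRUE)
  y <- ns$ad_add(ns$ad_mul(x, x), ns$ad_mul(x, 3))  # x^2 + 3x
  ns$ad_backward(y)
  expect_equal(x$grad, 2 * 2 + 3)
})

# independent numeric Parzen-NMI estimator with explicit (frozen) kernel
# constants; mirrors the estimator definition, not the tape implementation
oracle_soft_nmi <- function(x, y, cx, hx, cy, hy) {
  wts <- function(v, centers, h, lo, hi) {
    v <- pmin(pmax(as.vector(v), lo), hi)
    W <- exp(-outer(v, centers, "-")^2 / (2 * h^2))
    W / rowSums(W)
  }
  Wx <- wts(x, cx$centers, hx, cx$lo, cx$hi)
  Wy <- wts(y, cy$centers, hy, cy$lo, cy$hi)
  P <- t(Wx) %*% Wy / length(x)
  px <- rowSums(P); py <- colSums(P)
  eps <- 1e-12
  I <- sum(P * (log(P + eps) - log(outer(px, py) + eps)))
  Hx <- -sum(px * log(px + eps)); Hy <- -sum(py * log(py + eps))
  2 * I / (Hx + Hy)
}

parzen_constants <- function(v, K, bw = 1.5, clip = 3) {
  m <- mean(v); s <- stats::sd(v)
  lo <- m - clip * s; hi <- m + clip * s
  list(centers = seq(lo, hi, length.out = K), lo = lo, hi = hi,
       h = bw * (hi - lo) / (K - 1))
}

test_that("soft-NMI node matches an independent estimator and its frozen-constant gradient", {
  set.seed(14)
  K <- 8
  xs <- matrix(runif(64), 8)
  ys <- xs + matrix(rnorm(64, sd = 0.2), 8)
  cx <- parzen_constants(xs, K); cy <- parzen_constants(ys, K)
  xn <- ns$ad_tensor(array(xs, c(8, 8, 1)), requires_grad = TRUE)
  node <- ns$nmi_soft_node(xn, ns$ad_tensor(array(ys, c(8, 8, 1))), kernels = K)
  ns$ad_backward(node)
  # value agrees with the independent estimator
  expect_equal(ns$vof(node),
               oracle_soft_nmi(xs, ys, cx, cx$h, cy, cy$h), tolerance = 1e-10)
  # gradient agrees with finite differences of the frozen-constant estimator
  fo <- function(v) oracle_soft_nmi(matrix(v, 8), ys, cx, cx$h, cy, cy$h)
  expect_lt(max(abs(xn$grad[, , 1] - num_grad(fo, xs))), 1e-6)
})

test_that("GCC node gradient matches finite differences", {
  set.seed(15)
  xs <- matrix(runif(64), 8)
  ys <- xs + matrix(rnorm(64, sd = 0.2), 8)
  xg <- ns$ad_tensor(array(xs, c(8, 8, 1)), requires_grad = TRUE)
  gnode <- ns$gcc_node(xg, ns$ad_tensor(array(ys, c(8, 8, 1))))
  ns$ad_backward(gnode)
  fg <- function(v) gccAlignment(matrix(v, 8), ys)
  expect_lt(max(abs(xg$grad[, , 1] - num_grad(fg, xs))), 1e-5)
})
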