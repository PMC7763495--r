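# Shared fixtures: desk-scale network/training configurations and independent
# numerical oracles (finite differences, brute-force bilinear sampling,
# direct convolution) used to cross-check the package implementation.

ns <- getNamespace("dicyc")

tiny_gen_spec <- function()
  generatorSpec(baseChannels = 4L, downsampleChannels = c(8L, 16L),
                resnetBlocks = 2L)

tiny_trans_spec <- function()
  transformerSpec(reducerChannels = c(8L, 8L), hidden = 32L)

tiny_train_config <- function(...) {
  args <- list(generator = tiny_gen_spec(), transformer = tiny_trans_spec(),
               discriminatorBase = 8L, seed = 7L,
               epochsFixed = 1L, epochsDecay = 0L, iterationsPerEpoch = 2L)
  args <- utils::modifyList(args, list(...))
  do.call(trainConfig, args)
}

# overwrite a module's parameters with N(0, sd) draws (shape-preserving)
randomize_params <- function(params, sd = 0.3) {
  for (p in params) {
    v <- rnorm(length(p$value), sd = sd)
    if (!is.null(dim(p$value))) dim(v) <- dim(p$value)
    p$value <- v
  }
  invisible(params)
}

# central finite differences
num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    a <- x; a[i] <- a[i] + eps
    b <- x; b[i] <- b[i] - eps
    g[i] <- (f(a) - f(b)) / (2 * eps)
  }
  g
}

# brute-force bilinear sampler at normalized coordinates (independent of the
# compiled kernel): border padding, align-corners convention
oracle_bilinear <- function(x, grid) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, dim = c(H, W, C))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    px <- (grid[i, j, 1] + 1) / 2 * (W - 1)
    py <- (grid[i, j, 2] + 1) / 2 * (H - 1)
    px <- min(max(px, 0), W - 1); py <- min(max(py, 0), H - 1)
    x0 <- floor(px); y0 <- floor(py)
    wx <- px - x0; wy <- py - y0
    x1 <- min(x0 + 1, W - 1); y1 <- min(y0 + 1, H - 1)
    for (c in seq_len(C)) {
      out[i, j, c] <-
        (1 - wx) * (1 - wy) * x[y0 + 1, x0 + 1, c] +
        wx * (1 - wy)       * x[y0 + 1, x1 + 1, c] +
        (1 - wx) * wy       * x[y1 + 1, x0 + 1, c] +
        wx * wy             * x[y1 + 1, x1 + 1, c]
    }
  }
  out
}

# direct (loop) convolution with zero padding, independent oracle
oracle_conv <- function(x, w, b, stride = 1L, pad = 0L) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  out <- array(0, dim = c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) for (io in seq_len(Ho)) for (jo in seq_len(Wo)) {
    acc <- b[co]
    for (ci in seq_len(Cin)) for (p in seq_len(kh)) for (q in seq_len(kw)) {
      ii <- (io - 1) * stride - pad + p
      jj <- (jo - 1) * stride - pad + q
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, ci] * w[p, q, ci, co]
    }
    out[io, jo, co] <- acc
  }
  out
}

# smooth test image (sum of low-frequency sinusoids)
smooth_image <- function(H, W, seed = 1) {
  g <- identityGrid(H, W)
  set.seed(seed)
  a <- runif(3, 0.5, 1.5); ph <- runif(3, 0, 2 * pi)
  a[1] * sin(pi * g[, , 1] + ph[1]) + a[2] * cos(pi * g[, , 2] + ph[2]) +
    a[3] * sin(pi * (g[, , 1] + g[, , 2]) / 2 + ph[3])
}

constant_field <- function(H, W, dx, dy) {
  o <- array(0, dim = c(H, W, 2))
  o[, , 1] <- dx; o[, , 2] <- dy
  displacementField(o)
}
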