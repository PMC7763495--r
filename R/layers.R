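# Network building blocks on top of the autodiff tape: convolution and
# linear layers with weight containers, instance normalization, residual
# blocks, and an Adam optimizer. Layers are environments holding parameter
# nodes plus a forward closure; weights use the N(0, 0.02) initialization
# customary for this family of image translation networks.

new_layer <- function(kind, params, forward, desc) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- params
  e$forward <- forward
  e$desc <- desc
  class(e) <- "dicyc_layer"
  e
}

nn_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L,
                    pad_mode = "zero", init = c("gaussian", "zero"),
                    init_sd = 0.02) {
  init <- match.arg(init)
  wv <- if (init == "zero") array(0, dim = c(kh, kw, cin, cout))
        else array(stats::rnorm(kh * kw * cin * cout, sd = init_sd),
                   dim = c(kh, kw, cin, cout))
  w <- ad_param(wv)
  b <- ad_param(numeric(cout))
  desc <- list(kind = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
               stride = stride, pad = pad)
  new_layer("conv", list(w = w, b = b), function(x)
    ad_conv2d(x, w, b, stride = stride, pad = pad, pad_mode = pad_mode), desc)
}

nn_linear <- function(nin, nout, init = c("gaussian", "zero"), init_sd = 0.02) {
  init <- match.arg(init)
  wv <- if (init == "zero") matrix(0, nout, nin)
        else matrix(stats::rnorm(nin * nout, sd = init_sd), nout, nin)
  w <- ad_param(wv)
  b <- ad_param(numeric(nout))
  desc <- list(kind = "linear", nin = nin, nout = nout)
  new_layer("linear", list(w = w, b = b), function(x) ad_linear(x, w, b), desc)
}

nn_resnet_block <- function(channels, kernel = 3L) {
  pad <- (kernel - 1L) %/% 2L
  c1 <- nn_conv(kernel, kernel, channels, channels, pad = pad, pad_mode = "reflect")
  c2 <- nn_conv(kernel, kernel, channels, channels, pad = pad, pad_mode = "reflect")
  fwd <- function(x)
    ad_add(x, ad_instance_norm(c2$forward(ad_relu(ad_instance_norm(c1$forward(x))))))
  new_layer("resnet", c(c1$params, c2$params), fwd,
            list(kind = "resnet", convs = list(c1$desc, c2$desc)))
}

layer_params <- function(layers) {
  out <- list()
  for (l in layers) out <- c(out, l$params)
  out
}

# parameter count from a module's parameter list
params_count <- function(params) sum(vapply(params, function(p) length(p$value), 0))

# ---------------------------------------------------------------------------
# Adam
# ---------------------------------------------------------------------------

adam_new <- function(params, lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- lapply(params, function(p) p$value * 0)
  e$v <- lapply(params, function(p) p$value * 0)
  class(e) <- "dicyc_adam"
  e
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    p$value <- p$value - opt$lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  invisible(opt)
}

# snapshot / restore of parameter values and optimizer state (checkpointing)
params_values <- function(params) lapply(params, function(p) p$value)
params_restore <- function(params, values) {
  stopifnot(length(params) == length(values))
  for (i in seq_along(params)) params[[i]]$value <- values[[i]]
  invisible(params)
}
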