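#' @useDynLib dicyc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# A minimal reverse-mode automatic-differentiation tape over numeric arrays.
# Nodes are environments holding a value, an accumulated gradient, parent
# nodes and a backward closure mapping the node's gradient to parent
# gradients. Only what the synthesis networks need is implemented.
# ---------------------------------------------------------------------------

.ad <- new.env(parent = emptyenv())
.ad$epoch <- 0

ad_tensor <- function(value, requires_grad = FALSE, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) isTRUE(p$requires_grad), logical(1)))
  class(e) <- "ad_tensor"
  e
}

is_ad <- function(x) inherits(x, "ad_tensor")
ad_param <- function(value) ad_tensor(value, requires_grad = TRUE)
ad_wrap <- function(x) if (is_ad(x)) x else ad_tensor(x)
vof <- function(x) if (is_ad(x)) x$value else x

# Detach: constant node with the same value (blocks gradient flow).
ad_detach <- function(x) ad_tensor(vof(x))

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

#' @noRd
ad_backward <- function(root, seed = 1) {
  stopifnot(is_ad(root))
  if (!root$requires_grad) return(invisible(NULL))
  # iterative post-order DFS over grad-requiring nodes; visitation is marked
  # on the node with an epoch stamp (an id-keyed lookup table would intern a
  # fresh symbol per node, which R never frees)
  .ad$epoch <- .ad$epoch + 1
  epoch <- .ad$epoch
  topo <- vector("list", 256L); nt <- 0L
  stack <- vector("list", 256L)
  stack[[1L]] <- list(root, 0L); ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    node <- fr[[1L]]
    if (identical(node$.bw, epoch)) { ns <- ns - 1L; next }
    np <- length(node$parents)
    if (fr[[2L]] < np) {
      i <- fr[[2L]] + 1L
      stack[[ns]][[2L]] <- i
      ch <- node$parents[[i]]
      if (ch$requires_grad && !identical(ch$.bw, epoch)) {
        ns <- ns + 1L
        if (ns > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[ns]] <- list(ch, 0L)
      }
    } else {
      node$.bw <- epoch
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
      ns <- ns - 1L
    }
  }
  acc <- function(node, g) {
    if (is.null(g)) return()
    node$grad <- if (is.null(node$grad)) g else node$grad + g
  }
  root$grad <- if (length(root$value) == 1L) seed else array(seed, dim = dim(root$value))
  for (i in seq_len(nt)) {
    node <- topo[[nt - i + 1L]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      if (p$requires_grad && k <= length(gs)) acc(p, gs[[k]])
    }
  }
  invisible(NULL)
}

# -- shape helpers -----------------------------------------------------------

reduce_like <- function(g, ref) {
  if (length(ref) == 1L) sum(g) else g
}

# -- elementwise arithmetic --------------------------------------------------

ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_tensor(a$value + b$value, parents = list(a, b), backward = function(g)
    list(reduce_like(g, a$value), reduce_like(g, b$value)))
}

ad_sub <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_tensor(a$value - b$value, parents = list(a, b), backward = function(g)
    list(reduce_like(g, a$value), -reduce_like(g, b$value)))
}

ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_tensor(a$value * b$value, parents = list(a, b), backward = function(g)
    list(reduce_like(g * b$value, a$value), reduce_like(g * a$value, b$value)))
}

ad_div <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_tensor(a$value / b$value, parents = list(a, b), backward = function(g)
    list(reduce_like(g / b$value, a$value),
         reduce_like(-g * a$value / (b$value^2), b$value)))
}

ad_neg <- function(a) ad_sub(0, a)

ad_exp <- function(a) {
  a <- ad_wrap(a); y <- exp(a$value)
  ad_tensor(y, parents = list(a), backward = function(g) list(g * y))
}

ad_log <- function(a, eps = 0) {
  a <- ad_wrap(a)
  ad_tensor(log(a$value + eps), parents = list(a),
            backward = function(g) list(g / (a$value + eps)))
}

ad_sqrt <- function(a, eps = 0) {
  a <- ad_wrap(a); y <- sqrt(a$value + eps)
  ad_tensor(y, parents = list(a), backward = function(g) list(g * 0.5 / y))
}

ad_abs <- function(a) {
  a <- ad_wrap(a)
  ad_tensor(abs(a$value), parents = list(a),
            backward = function(g) list(g * sign(a$value)))
}

ad_relu <- function(a) {
  a <- ad_wrap(a); m <- a$value > 0
  ad_tensor(a$value * m, parents = list(a), backward = function(g) list(g * m))
}

ad_lrelu <- function(a, slope = 0.2) {
  a <- ad_wrap(a); m <- ifelse(a$value > 0, 1, slope)
  ad_tensor(a$value * m, parents = list(a), backward = function(g) list(g * m))
}

ad_tanh <- function(a) {
  a <- ad_wrap(a); y <- tanh(a$value)
  ad_tensor(y, parents = list(a), backward = function(g) list(g * (1 - y^2)))
}

ad_clamp <- function(a, lo, hi) {
  a <- ad_wrap(a)
  m <- a$value >= lo & a$value <= hi
  ad_tensor(pmin(pmax(a$value, lo), hi), parents = list(a),
            backward = function(g) list(g * m))
}

# -- reductions --------------------------------------------------------------

ad_sum <- function(a) {
  a <- ad_wrap(a); d <- dim(a$value); n <- length(a$value)
  ad_tensor(sum(a$value), parents = list(a), backward = function(g)
    list(if (is.null(d)) rep(g, n) else array(g, dim = d)))
}

ad_mean <- function(a) {
  a <- ad_wrap(a); d <- dim(a$value); n <- length(a$value)
  ad_tensor(mean(a$value), parents = list(a), backward = function(g)
    list(if (is.null(d)) rep(g / n, n) else array(g / n, dim = d)))
}

# -- linear algebra ----------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_tensor(a$value %*% b$value, parents = list(a, b), backward = function(g)
    list(g %*% t(b$value), t(a$value) %*% g))
}

ad_transpose <- function(a) {
  a <- ad_wrap(a)
  ad_tensor(t(a$value), parents = list(a), backward = function(g) list(t(g)))
}

ad_rowsums <- function(a) {
  a <- ad_wrap(a); d <- dim(a$value)
  ad_tensor(rowSums(a$value), parents = list(a), backward = function(g)
    list(matrix(g, nrow = d[1], ncol = d[2])))
}

ad_colsums <- function(a) {
  a <- ad_wrap(a); d <- dim(a$value)
  ad_tensor(colSums(a$value), parents = list(a), backward = function(g)
    list(matrix(g, nrow = d[1], ncol = d[2], byrow = TRUE)))
}

# outer difference x[i] - centers[k] -> N x K matrix (centers constant)
ad_outer_diff <- function(x, centers) {
  x <- ad_wrap(x)
  v <- outer(as.vector(x$value), centers, "-")
  ad_tensor(v, parents = list(x), backward = function(g) list(rowSums(g)))
}

# y = W x + b for a vector x
ad_linear <- function(x, W, b) {
  x <- ad_wrap(x); W <- ad_wrap(W); b <- ad_wrap(b)
  y <- as.vector(W$value %*% as.vector(x$value)) + b$value
  ad_tensor(y, parents = list(x, W, b), backward = function(g) {
    g <- as.vector(g)
    list(as.vector(t(W$value) %*% g), outer(g, as.vector(x$value)), g)
  })
}

ad_reshape <- function(a, dims) {
  a <- ad_wrap(a); old <- dim(a$value)
  v <- a$value; dim(v) <- dims
  ad_tensor(v, parents = list(a), backward = function(g) {
    dim(g) <- old
    list(g)
  })
}

# -- image / feature-map ops -------------------------------------------------

# concatenate along the channel (third) dimension
ad_concat_c <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1] == db[1], da[2] == db[2])
  v <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db[3]))
  ad_tensor(v, parents = list(a, b), backward = function(g)
    list(array(g[, , seq_len(da[3])], dim = da),
         array(g[, , da[3] + seq_len(db[3])], dim = db)))
}

# instance normalization without learned affine (per-channel, eps inside sqrt)
ad_instance_norm <- function(a, eps = 1e-5) {
  a <- ad_wrap(a); x <- a$value
  d <- dim(x); n <- d[1] * d[2]
  xm <- x; dim(xm) <- c(n, d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  sig <- sqrt(colMeans(xc * xc) + eps)
  ym <- xc / rep(sig, each = n)
  y <- ym; dim(y) <- d
  ad_tensor(y, parents = list(a), backward = function(g) {
    gm_ <- g; dim(gm_) <- c(n, d[3])
    gmean <- colMeans(gm_)
    gymean <- colMeans(gm_ * ym)
    gx <- (gm_ - rep(gmean, each = n) - ym * rep(gymean, each = n)) /
      rep(sig, each = n)
    dim(gx) <- d
    list(gx)
  })
}

# global average pooling (H,W,C) -> length-C vector
ad_gap <- function(a) {
  a <- ad_wrap(a); d <- dim(a$value); n <- d[1] * d[2]
  xm <- a$value; dim(xm) <- c(n, d[3])
  ad_tensor(colMeans(xm), parents = list(a), backward = function(g) {
    gx <- rep(g / n, each = n)
    dim(gx) <- d
    list(gx)
  })
}

# nearest-neighbour 2x upsampling
ad_upsample2 <- function(a) {
  a <- ad_wrap(a); d <- dim(a$value)
  idx_i <- rep(seq_len(d[1]), each = 2)
  idx_j <- rep(seq_len(d[2]), each = 2)
  v <- a$value[idx_i, idx_j, , drop = FALSE]
  ad_tensor(v, parents = list(a), backward = function(g) {
    gx <- array(0, dim = d)
    for (di in 0:1) for (dj in 0:1)
      gx <- gx + g[seq(1 + di, 2 * d[1], by = 2), seq(1 + dj, 2 * d[2], by = 2), , drop = FALSE]
    list(gx)
  })
}

# -- compiled-kernel ops -----------------------------------------------------

pad_mode_code <- function(mode) {
  switch(mode, zero = 0L, zeros = 0L, reflect = 1L, border = 1L,
         stop("unknown padding mode: ", mode))
}

ad_conv2d <- function(x, w, b, stride = 1L, pad = 0L, pad_mode = "zero") {
  x <- ad_wrap(x); w <- ad_wrap(w); b <- ad_wrap(b)
  pm <- if (pad_mode == "reflect") 1L else 0L
  if (!w$requires_grad && !b$requires_grad && !x$requires_grad) {
    # constant path: no need to cache the patch matrix
    return(ad_tensor(cpp_conv2d_fw(x$value, w$value, b$value,
                                   as.integer(stride), as.integer(pad), pm)))
  }
  fw <- cpp_conv2d_fwm(x$value, w$value, b$value, as.integer(stride),
                       as.integer(pad), pm)
  need_gx <- x$requires_grad
  xdim <- dim(x$value)
  ad_tensor(fw$y, parents = list(x, w, b), backward = function(g) {
    r <- cpp_conv2d_bwm(fw$M, xdim, w$value, g, as.integer(stride),
                        as.integer(pad), pm, need_gx)
    list(if (need_gx) r$gx else NULL, r$gw, r$gb)
  })
}

# bilinear sampling at absolute normalized coordinates; grid is (H,W,2)
ad_grid_sample <- function(x, grid, padding = "border") {
  x <- ad_wrap(x); grid <- ad_wrap(grid)
  pm <- if (padding == "border") 1L else 0L
  y <- cpp_grid_sample_fw(x$value, grid$value, pm)
  ad_tensor(y, parents = list(x, grid), backward = function(g) {
    r <- cpp_grid_sample_bw(x$value, grid$value, g, pm)
    list(r$gx, r$ggrid)
  })
}
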