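# Quantitative and qualitative evaluation: MSE / PSNR / SSIM (computed
# globally over the evaluated region, optionally restricted to a mask),
# paired t-tests, checkerboard and signed error images, and model-complexity
# accounting (trainable parameters and multiply-add operations).

#' Image-quality metrics between a synthesized image and its reference
#'
#' MSE is the mean squared voxel difference; PSNR is
#' `10 log10(max_ref^2 / MSE)` with `max_ref` the maximum voxel value of the
#' reference over the evaluated region (`Inf` when MSE is 0); SSIM is the
#' global structural similarity
#' `(2 mu_x mu_r + c1)(2 cov + c2) / ((mu_x^2 + mu_r^2 + c1)(var_x + var_r + c2))`
#' with the conventional stabilizers `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`,
#' `L` the reference dynamic range. A windowed SSIM variant is available via
#' `windowed = TRUE` (8x8 moving average) but the global form is the default.
#'
#' @param x synthesized [ImageSlice-class], matrix or array.
#' @param reference ground-truth image of the same shape.
#' @param mask optional logical/0-1 grid restricting the evaluation.
#' @param maskName optional label stored in the report.
#' @param windowed use a windowed SSIM average instead of the global form.
#' @return A [MetricsReport-class].
#' @export
synthMetrics <- function(x, reference, mask = NULL, maskName = NULL,
                         windowed = FALSE) {
  xv <- as_pix(x); rv <- as_pix(reference)
  if (!all(dim(xv) == dim(rv))) stop("shape mismatch between x and reference")
  if (!is.null(mask)) {
    mk <- as_pix(mask) != 0
    if (!all(dim(mk) == dim(xv))) stop("mask shape mismatch")
    if (!any(mk)) stop("empty mask")
    xs <- xv[mk]; rs <- rv[mk]
  } else {
    xs <- as.vector(xv); rs <- as.vector(rv)
  }
  n <- length(xs)
  mse <- mean((xs - rs)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(max(rs)^2 / mse)
  L <- diff(range(rs))
  if (L == 0) L <- 1
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  if (windowed && is.null(mask)) {
    ssim <- ssim_windowed(xv, rv, c1, c2)
  } else {
    mx <- mean(xs); mr <- mean(rs)
    vx <- mean((xs - mx)^2); vr <- mean((rs - mr)^2)
    cv <- mean((xs - mx) * (rs - mr))
    ssim <- ((2 * mx * mr + c1) * (2 * cv + c2)) /
      ((mx^2 + mr^2 + c1) * (vx + vr + c2))
  }
  new("MetricsReport", mse = mse, psnr = psnr, ssim = ssim,
      nVoxels = as.integer(n),
      maskName = if (is.null(maskName)) NA_character_ else maskName)
}

ssim_windowed <- function(x, r, c1, c2, win = 8L) {
  box <- array(1 / win^2, dim = c(win, win, 1, 1))
  mu <- function(m) cpp_conv2d_fw(array(m, dim = c(dim(m), 1L)), box,
                                  0, 1L, 0L, 0L)
  mx <- mu(x); mr <- mu(r)
  vx <- mu(x * x) - mx^2; vr <- mu(r * r) - mr^2
  cv <- mu(x * r) - mx * mr
  mean(((2 * mx * mr + c1) * (2 * cv + c2)) /
         ((mx^2 + mr^2 + c1) * (vx + vr + c2)))
}

#' Classical two-sided paired t-test
#'
#' @param valuesA,valuesB paired metric values of equal length (>= 2).
#' @return List with elements `t` and `p`.
#' @export
pairedTTest <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB) || length(valuesA) < 2)
    stop("need two equal-length vectors with at least 2 pairs")
  d <- valuesA - valuesB
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t-test is degenerate")
  ht <- stats::t.test(valuesA, valuesB, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Checkerboard visualization of two images
#'
#' Alternating square tiles taken from the two images, the standard visual
#' check of cross-modality alignment.
#'
#' @param x,y [ImageSlice-class] objects or matrices of the same shape.
#' @param tile tile side in pixels (>= 1).
#' @return An [ImageSlice-class].
#' @export
checkerboard <- function(x, y, tile = 8L) {
  xm <- as_pix(x); ym <- as_pix(y)
  if (!all(dim(xm) == dim(ym))) stop("shape mismatch")
  if (tile < 1) stop("tile must be >= 1")
  ti <- ceiling(row(xm) / tile); tj <- ceiling(col(xm) / tile)
  out <- ifelse((ti + tj) %% 2 == 0, xm, ym)
  imageSlice(out, id = "checkerboard")
}

#' Signed error image
#'
#' @param x image under evaluation.
#' @param reference ground truth of the same shape.
#' @return An [ImageSlice-class] holding `x - reference`; use [errorScale()]
#'   for the symmetric color limit.
#' @export
errorImage <- function(x, reference) {
  xm <- as_pix(x); rm_ <- as_pix(reference)
  if (!all(dim(xm) == dim(rm_))) stop("shape mismatch")
  imageSlice(xm - rm_, id = "error")
}

#' Symmetric color limit of an error image
#' @param x an error [ImageSlice-class].
#' @return `max(abs(pixels))`, the symmetric display range.
#' @export
errorScale <- function(x) max(abs(pixels(x)))

#' Count trainable parameters of a network handle
#'
#' @param network a handle from [buildGenerator()], [buildTransformer()] or
#'   [buildDiscriminator()].
#' @return Number of trainable scalar parameters.
#' @export
countParameters <- function(network) {
  stopifnot(!is.null(network$params))
  params_count(network$params)
}

#' Count multiply-add operations of one forward pass
#'
#' One MAC per kernel-element multiply; normalization, activations and
#' interpolation are excluded, as is conventional. For generators the
#' `"deformed"` pass adds the offset convolutions at their insertion scales.
#'
#' @param network a network handle.
#' @param inputShape integer `(H, W)` of the input.
#' @param pass `"undeformed"` (prediction path, default) or `"deformed"`.
#' @return MAC count.
#' @export
countMACs <- function(network, inputShape, pass = c("undeformed", "deformed")) {
  pass <- match.arg(pass)
  walk <- function(arch, H, W) {
    macs <- 0
    for (d in arch) {
      if (d$kind == "conv") {
        H <- (H + 2 * d$pad - d$kh) %/% d$stride + 1
        W <- (W + 2 * d$pad - d$kw) %/% d$stride + 1
        macs <- macs + as.numeric(H) * W * d$cout * d$kh * d$kw * d$cin
      } else if (d$kind == "upsample2") {
        H <- 2 * H; W <- 2 * W
      } else if (d$kind == "linear") {
        macs <- macs + as.numeric(d$nin) * d$nout
      }
    }
    macs
  }
  total <- walk(network$arch, inputShape[1], inputShape[2])
  if (pass == "deformed" && !is.null(network$arch_offsets)) {
    scales <- c(1L, 1L, 2L, 4L)   # insertion points: input, post-e1, post-e2, post-e3
    for (i in seq_along(network$arch_offsets)) {
      d <- network$arch_offsets[[i]]
      H <- inputShape[1] %/% scales[i]; W <- inputShape[2] %/% scales[i]
      total <- total + as.numeric(H) * W * d$cout * d$kh * d$kw * d$cin
    }
  }
  total
}

#' Summarize per-image metric rows into a report table
#'
#' @param rows data.frame with columns `method` and metric columns `mse`,
#'   `psnr`, `ssim`.
#' @return data.frame of means and standard deviations per method.
#' @export
metricsSummary <- function(rows) {
  stopifnot(all(c("method", "mse", "psnr", "ssim") %in% names(rows)))
  agg <- function(f) stats::aggregate(rows[c("mse", "psnr", "ssim")],
                                      by = list(method = rows$method), FUN = f)
  m <- agg(mean); s <- agg(stats::sd)
  names(s)[-1] <- paste0(names(s)[-1], "_sd")
  merge(m, s, by = "method")
}
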