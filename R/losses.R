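# Loss terms: least-squares adversarial losses, normalized mutual
# information (hard-binned for evaluation, Parzen soft-binned and
# differentiable for training), gradient cross-correlation, the two
# cycle-consistency losses and the weighted total. The alignment loss is
# computed on the UNDEFORMED outputs only and the adversarial losses on the
# DEFORMED outputs only; this split is what removes the gradient conflict
# between alignment and adversarial objectives.

as_pix <- function(x) if (is(x, "ImageSlice")) pixels(x) else x

#' Least-squares discriminator loss
#'
#' `mean((d_real - 1)^2) / 2 + mean(d_fake^2) / 2`. The logistic
#' (cross-entropy) form is available via `form = "log"`.
#'
#' @param dReal,dFake discriminator patch maps of equal shape.
#' @param form `"lsgan"` (default) or `"log"`.
#' @return Scalar loss.
#' @export
lsganDiscriminatorLoss <- function(dReal, dFake, form = c("lsgan", "log")) {
  form <- match.arg(form)
  dReal <- as_pix(dReal); dFake <- as_pix(dFake)
  if (!all(dim(dReal) == dim(dFake))) stop("patch map shape mismatch")
  if (form == "lsgan") mean((dReal - 1)^2) / 2 + mean(dFake^2) / 2
  else -mean(log(dReal + 1e-12)) / 2 - mean(log(1 - dFake + 1e-12)) / 2
}

#' Least-squares generator loss
#'
#' `mean((d_fake - 1)^2)`, evaluated on the discriminator's response to the
#' DEFORMED synthesized output.
#'
#' @param dFake discriminator patch map on a synthesized image.
#' @param form `"lsgan"` (default) or `"log"`.
#' @return Scalar loss.
#' @export
lsganGeneratorLoss <- function(dFake, form = c("lsgan", "log")) {
  form <- match.arg(form)
  dFake <- as_pix(dFake)
  if (form == "lsgan") mean((dFake - 1)^2)
  else -mean(log(dFake + 1e-12))
}

hard_bin <- function(x, bins, binning) {
  if (binning == "rank") {
    b <- ceiling(rank(x, ties.method = "average") / length(x) * bins)
    pmin(pmax(b, 1), bins)
  } else {
    lo <- min(x); hi <- max(x)
    if (hi == lo) return(rep(1L, length(x)))
    b <- findInterval(x, seq(lo, hi, length.out = bins + 1),
                      all.inside = TRUE)
    b
  }
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information of two images
#'
#' `NMI = 2 I(X;Y) / (H(X) + H(Y))`, in `[0, 1]`: 1 for perfectly dependent
#' equal-entropy images, 0 for independent ones. The `hard` mode uses a joint
#' histogram (equal-width bins by default; `binning = "rank"` uses
#' equal-frequency bins, making the value invariant to strictly monotone
#' intensity transformations). The `soft` mode uses Parzen binning with
#' Gaussian kernels (bandwidth 1.5 bin widths over intensities clipped to
#' 3 standard deviations), the same estimator the differentiable training
#' loss uses. A constant image has zero entropy; NMI is then defined as 0
#' with a warning.
#'
#' @param x,y [ImageSlice-class] objects or numeric matrices of equal shape.
#' @param bins number of bins (hard) or kernels (soft); default 64 hard / 32 soft.
#' @param mode `"hard"` or `"soft"`.
#' @param binning `"width"` or `"rank"` (hard mode only).
#' @return NMI in `[0, 1]`.
#' @export
normalizedMutualInformation <- function(x, y, bins = NULL,
                                        mode = c("hard", "soft"),
                                        binning = c("width", "rank")) {
  mode <- match.arg(mode); binning <- match.arg(binning)
  x <- as.vector(as_pix(x)); y <- as.vector(as_pix(y))
  if (length(x) != length(y)) stop("images must have the same shape")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant image: NMI defined as 0")
    return(0)
  }
  if (is.null(bins)) bins <- if (mode == "hard") 64L else 32L
  if (bins < 2) stop("bins must be >= 2")
  if (mode == "hard") {
    bx <- hard_bin(x, bins, binning); by <- hard_bin(y, bins, binning)
    P <- as.matrix(table(factor(bx, levels = 1:bins),
                         factor(by, levels = 1:bins))) / length(x)
    px <- rowSums(P); py <- colSums(P)
    I <- entropy_nats(px) + entropy_nats(py) - entropy_nats(as.vector(P))
    2 * I / (entropy_nats(px) + entropy_nats(py))
  } else {
    vof(nmi_soft_node(ad_tensor(x), ad_tensor(y), kernels = bins))
  }
}

# Parzen soft-binned NMI on tape nodes (differentiable in both images).
# Kernel centers and bandwidth are computed from the current values and
# treated as constants of the estimator.
nmi_soft_node <- function(x, y, kernels = 32L, bandwidthFactor = 1.5,
                          clipSd = 3) {
  parzen_weights <- function(v) {
    val <- as.vector(vof(v))
    m <- mean(val); s <- stats::sd(val)
    if (s == 0) s <- 1
    lo <- m - clipSd * s; hi <- m + clipSd * s
    centers <- seq(lo, hi, length.out = kernels)
    h <- bandwidthFactor * (hi - lo) / (kernels - 1)
    flat <- ad_reshape(v, length(val))
    D <- ad_outer_diff(ad_clamp(flat, lo, hi), centers)
    Wu <- ad_exp(ad_mul(ad_mul(D, D), -1 / (2 * h^2)))
    rs <- ad_rowsums(Wu)
    ad_div(Wu, ad_matmul(ad_reshape(rs, c(length(val), 1L)),
                         ad_tensor(matrix(1, 1, kernels))))
  }
  n <- length(vof(x))
  Wx <- parzen_weights(x); Wy <- parzen_weights(y)
  P <- ad_mul(ad_matmul(ad_transpose(Wx), Wy), 1 / n)
  px <- ad_rowsums(P); py <- ad_colsums(P)
  eps <- 1e-12
  K <- kernels
  prod_marg <- ad_matmul(ad_reshape(px, c(K, 1L)), ad_reshape(py, c(1L, K)))
  I <- ad_sum(ad_mul(P, ad_sub(ad_log(P, eps), ad_log(prod_marg, eps))))
  Hx <- ad_neg(ad_sum(ad_mul(px, ad_log(px, eps))))
  Hy <- ad_neg(ad_sum(ad_mul(py, ad_log(py, eps))))
  ad_div(ad_mul(I, 2), ad_add(Hx, Hy))
}

grad_kernels <- function() {
  kx <- array(0, dim = c(3, 3, 1, 1)); kx[2, 1, 1, 1] <- -0.5; kx[2, 3, 1, 1] <- 0.5
  ky <- array(0, dim = c(3, 3, 1, 1)); ky[1, 2, 1, 1] <- -0.5; ky[3, 2, 1, 1] <- 0.5
  list(kx = kx, ky = ky)
}

ncc_abs_node <- function(a, b, eps = 1e-8) {
  ac <- ad_sub(a, ad_mean(a)); bc <- ad_sub(b, ad_mean(b))
  num <- ad_mean(ad_mul(ac, bc))
  den <- ad_add(ad_mul(ad_sqrt(ad_mean(ad_mul(ac, ac))),
                       ad_sqrt(ad_mean(ad_mul(bc, bc)))), eps)
  ad_abs(ad_div(num, den))
}

gcc_node <- function(x, y) {
  k <- grad_kernels()
  zb <- numeric(1)
  gxx <- ad_conv2d(x, ad_tensor(k$kx), ad_tensor(zb), pad = 1L, pad_mode = "reflect")
  gxy <- ad_conv2d(x, ad_tensor(k$ky), ad_tensor(zb), pad = 1L, pad_mode = "reflect")
  gyx <- ad_conv2d(y, ad_tensor(k$kx), ad_tensor(zb), pad = 1L, pad_mode = "reflect")
  gyy <- ad_conv2d(y, ad_tensor(k$ky), ad_tensor(zb), pad = 1L, pad_mode = "reflect")
  ad_mul(ad_add(ncc_abs_node(gxx, gyx), ncc_abs_node(gxy, gyy)), 0.5)
}

#' Gradient cross-correlation alignment measure
#'
#' Mean of the absolute normalized cross-correlations of the horizontal and
#' vertical gradient images; 1 for identical (or inverted) images, 0 when
#' gradients are uncorrelated.
#'
#' @param x,y [ImageSlice-class] objects or matrices of equal shape.
#' @return Value in `[0, 1]`.
#' @export
gccAlignment <- function(x, y) {
  xm <- as_pix(x); ym <- as_pix(y)
  if (!all(dim(xm) == dim(ym))) stop("images must have the same shape")
  if (stats::sd(as.vector(xm)) == 0 || stats::sd(as.vector(ym)) == 0) {
    warning("zero-gradient image: GCC defined as 0")
    return(0)
  }
  xa <- ad_tensor(array(xm, dim = c(dim(xm), 1L)))
  ya <- ad_tensor(array(ym, dim = c(dim(ym), 1L)))
  vof(gcc_node(xa, ya))
}

# ---------------------------------------------------------------------------
# pluggable alignment-measure registry
# ---------------------------------------------------------------------------

.align_registry <- new.env(parent = emptyenv())

#' Register a plugin alignment measure
#'
#' A measure maps two tape nodes (or two matrices) to a similarity in
#' `[0, 1]`. Registered plugins are selectable in configurations with the key
#' `"plugin:<name>"`. A slot for the modality-independent neighbourhood
#' descriptor (MIND) can be filled this way; the descriptor itself is not
#' shipped.
#'
#' @param name plugin name.
#' @param fn function of two arguments returning a similarity in `[0, 1]`.
#' @export
registerAlignmentMeasure <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .align_registry[[name]] <- fn
  invisible(name)
}

#' Resolve an alignment measure by configuration key
#'
#' @param key `"nmi"`, `"gcc"` or `"plugin:<name>"`.
#' @param differentiable return the tape-node version (internal use).
#' @return A function of two images.
#' @export
alignmentMeasure <- function(key = "nmi", differentiable = FALSE) {
  if (startsWith(key, "plugin:")) {
    nm <- sub("^plugin:", "", key)
    fn <- .align_registry[[nm]]
    if (is.null(fn)) stop("no registered alignment measure '", nm, "'")
    return(fn)
  }
  switch(key,
    nmi = if (differentiable) nmi_soft_node else
      function(x, y) normalizedMutualInformation(x, y, mode = "hard"),
    gcc = if (differentiable) gcc_node else gccAlignment,
    stop("unknown alignment measure: ", key))
}

#' Image alignment loss
#'
#' `2 - m(xA, xhatB) - m(xB, xhatA)` where `m` is an alignment measure scaled
#' to `[0, 1]` and the synthesized images are the UNDEFORMED outputs of the
#' two generator directions. Nonnegative; 0 iff both measures are maximal.
#'
#' @param xA,xB source images of the two domains.
#' @param synthABUndeformed undeformed synthesis of `xA` (domain-B looking).
#' @param synthBAUndeformed undeformed synthesis of `xB`.
#' @param measure `"nmi"` (default), `"gcc"`, `"plugin:<name>"` or a function.
#' @return Scalar loss in `[0, 2]`.
#' @export
alignmentLoss <- function(xA, synthABUndeformed, xB, synthBAUndeformed,
                          measure = "nmi") {
  m <- if (is.function(measure)) measure else alignmentMeasure(measure)
  m1 <- m(xA, synthABUndeformed)
  m2 <- m(xB, synthBAUndeformed)
  if (any(c(m1, m2) < -1e-9) || any(c(m1, m2) > 1 + 1e-9))
    stop("alignment measure returned a value outside [0, 1]")
  2 - m1 - m2
}

mae <- function(a, b) mean(abs(as_pix(a) - as_pix(b)))

#' Cycle-consistency loss (undeformed passes)
#'
#' Sum of the two mean absolute reconstruction errors of the undeformed
#' round trips A -> B -> A and B -> A -> B.
#'
#' @param xA,xB originals; `cycledA`, `cycledB` their round-trip
#'   reconstructions through the undeformed passes.
#' @param cycledA,cycledB reconstructed images.
#' @return Scalar loss.
#' @export
cycleLoss <- function(xA, cycledA, xB, cycledB) {
  if (!all(dim(as_pix(xA)) == dim(as_pix(cycledA))) ||
      !all(dim(as_pix(xB)) == dim(as_pix(cycledB))))
    stop("cycleLoss: shape mismatch")
  mae(xA, cycledA) + mae(xB, cycledB)
}

#' Deformation-invariant cycle-consistency loss (deformed passes)
#'
#' Same functional form as [cycleLoss()], applied to the round trips through
#' the DEFORMED passes (the deformation-bearing compositions).
#'
#' @inheritParams cycleLoss
#' @param cycledADeformed,cycledBDeformed deformed-pass round trips.
#' @return Scalar loss.
#' @export
dicycLoss <- function(xA, cycledADeformed, xB, cycledBDeformed) {
  cycleLoss(xA, cycledADeformed, xB, cycledBDeformed)
}

#' Weighted total loss with full breakdown
#'
#' `total = ganAB + ganBA + lambdaAlign * align + lambdaCyc * cyc +
#'  lambdaDicyc * dicyc`, the exact identity preserved in the returned
#' [LossBreakdown-class].
#'
#' @param ganAB,ganBA,align,cyc,dicyc the five loss parts (finite).
#' @param weights a [LossWeights-class].
#' @return A [LossBreakdown-class].
#' @export
totalLoss <- function(ganAB, ganBA, align, cyc, dicyc,
                      weights = lossWeights()) {
  parts <- c(ganAB = ganAB, ganBA = ganBA, align = align, cyc = cyc,
             dicyc = dicyc)
  bad <- names(parts)[!is.finite(parts)]
  if (length(bad)) stop("non-finite loss term: ", paste(bad, collapse = ", "))
  total <- ganAB + ganBA + weights@lambdaAlign * align +
    weights@lambdaCyc * cyc + weights@lambdaDicyc * dicyc
  new("LossBreakdown", ganAB = ganAB, ganBA = ganBA, align = align,
      cyc = cyc, dicyc = dicyc, total = total, weights = weights)
}

# tape-node loss helpers used by the training loop ---------------------------

lsgan_d_node <- function(dReal, dFake) {
  a <- ad_mul(ad_mean(ad_mul(ad_sub(dReal, 1), ad_sub(dReal, 1))), 0.5)
  b <- ad_mul(ad_mean(ad_mul(dFake, dFake)), 0.5)
  ad_add(a, b)
}

lsgan_g_node <- function(dFake) {
  d <- ad_sub(dFake, 1)
  ad_mean(ad_mul(d, d))
}

mae_node <- function(a, b) ad_mean(ad_abs(ad_sub(a, b)))
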