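# S4 containers for images, deformation fields and results.

#' Single-channel 2-D image slice
#'
#' Container for one grayscale image slice with a domain label. Intensities
#' are stored as a numeric H x W matrix; after preprocessing with
#' [normalizeSlice()] they have zero mean and unit standard deviation.
#'
#' @slot pixels numeric H x W matrix of intensities (arbitrary units).
#' @slot domain domain label, `"A"` or `"B"`.
#' @slot spacing in-plane voxel spacing in millimetres, length 2.
#' @slot id identifier string.
#' @export
setClass("ImageSlice",
  representation(pixels = "matrix", domain = "character",
                 spacing = "numeric", id = "character"),
  prototype(domain = "A", spacing = c(1, 1), id = ""))

setValidity("ImageSlice", function(object) {
  p <- object@pixels
  if (nrow(p) < 16 || ncol(p) < 16) return("image must be at least 16 x 16")
  if (!all(is.finite(p))) return("pixel values must be finite")
  if (!object@domain %in% c("A", "B")) return("domain must be 'A' or 'B'")
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    return("spacing must be two positive numbers")
  TRUE
})

#' Construct an ImageSlice
#'
#' @param pixels numeric matrix (at least 16 x 16).
#' @param domain `"A"` or `"B"`.
#' @param spacing in-plane spacing (mm), length 2.
#' @param id identifier string.
#' @return An [ImageSlice-class] object.
#' @export
imageSlice <- function(pixels, domain = "A", spacing = c(1, 1), id = "") {
  new("ImageSlice", pixels = as.matrix(pixels), domain = domain,
      spacing = as.numeric(spacing), id = as.character(id))
}

#' @describeIn imageSlice Extract the pixel matrix.
#' @param x an `ImageSlice`.
#' @export
pixels <- function(x) {
  stopifnot(is(x, "ImageSlice"))
  x@pixels
}

#' @describeIn imageSlice Domain label of a slice.
#' @export
domainLabel <- function(x) {
  stopifnot(is(x, "ImageSlice"))
  x@domain
}

#' Normalize a slice to zero mean and unit standard deviation
#'
#' @param x an [ImageSlice-class].
#' @return An `ImageSlice` with standardized intensities.
#' @export
normalizeSlice <- function(x) {
  p <- pixels(x)
  s <- stats::sd(as.vector(p))
  if (s == 0) stop("cannot normalize a constant image")
  imageSlice((p - mean(p)) / s, domain = x@domain, spacing = x@spacing, id = x@id)
}

setMethod("show", "ImageSlice", function(object) {
  p <- object@pixels
  cat(sprintf("ImageSlice '%s' [domain %s] %d x %d, range [%.3g, %.3g]\n",
              object@id, object@domain, nrow(p), ncol(p), min(p), max(p)))
})

#' Dense 2-D displacement field
#'
#' Per-pixel displacement in normalized `[-1, 1]` coordinates (align-corners
#' convention: -1 and 1 are the centers of the first and last pixel). The
#' displacement is added to the identity sampling grid, so the zero field is
#' the identity resampling. Channel 1 holds x (width-direction) offsets and
#' channel 2 holds y (height-direction) offsets.
#'
#' @slot offsets numeric H x W x 2 array of displacements (dimensionless).
#' @export
setClass("DisplacementField", representation(offsets = "array"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@offsets)
  if (length(d) != 3 || d[3] != 2) return("offsets must be an H x W x 2 array")
  if (!all(is.finite(object@offsets))) return("offsets must be finite")
  TRUE
})

#' Construct a DisplacementField
#'
#' @param offsets H x W x 2 numeric array of normalized displacements.
#' @return A [DisplacementField-class].
#' @export
displacementField <- function(offsets) new("DisplacementField", offsets = offsets)

#' Zero (identity) displacement field
#' @param H,W spatial dimensions.
#' @export
zeroField <- function(H, W) displacementField(array(0, dim = c(H, W, 2)))

#' @describeIn displacementField Extract the offset array.
#' @param x a `DisplacementField`.
#' @export
fieldOffsets <- function(x) {
  stopifnot(is(x, "DisplacementField"))
  x@offsets
}

#' Mean absolute displacement magnitude of a field
#' @param x a [DisplacementField-class].
#' @return Mean of the per-pixel Euclidean displacement norm (normalized units).
#' @export
meanDisplacement <- function(x) {
  o <- fieldOffsets(x)
  mean(sqrt(o[, , 1]^2 + o[, , 2]^2))
}

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@offsets)
  cat(sprintf("DisplacementField %d x %d, mean |u| = %.4g, max |u| = %.4g\n",
              d[1], d[2], meanDisplacement(object), max(abs(object@offsets))))
})

#' Set of spatial control points in normalized coordinates
#'
#' @slot points N x 2 matrix of coordinates, each in `[-1, 1]`
#'   (column 1 = x, column 2 = y).
#' @slot layout `"regular-grid"` or `"free"`.
#' @export
setClass("ControlPointSet",
  representation(points = "matrix", layout = "character"),
  prototype(layout = "free"))

setValidity("ControlPointSet", function(object) {
  p <- object@points
  if (nrow(p) < 3 || ncol(p) != 2) return("need an N x 2 matrix with N >= 3")
  if (any(!is.finite(p)) || any(abs(p) > 1 + 1e-12))
    return("coordinates must be finite and in [-1, 1]")
  if (object@layout == "regular-grid" &&
      round(sqrt(nrow(p)))^2 != nrow(p))
    return("regular-grid layout requires N = n^2 points")
  TRUE
})

#' Construct a ControlPointSet
#' @param points N x 2 matrix in `[-1, 1]`.
#' @param layout `"regular-grid"` or `"free"`.
#' @export
controlPointSet <- function(points, layout = "free")
  new("ControlPointSet", points = as.matrix(points), layout = layout)

#' @describeIn controlPointSet Extract the coordinate matrix.
#' @param x a `ControlPointSet`.
#' @export
controlPoints <- function(x) {
  stopifnot(is(x, "ControlPointSet"))
  x@points
}

setMethod("show", "ControlPointSet", function(object) {
  cat(sprintf("ControlPointSet: %d points (%s layout)\n",
              nrow(object@points), object@layout))
})

#' Thin-plate-spline mapping coefficients
#'
#' The fitted map is \eqn{\Phi(t) = c + A t + W^T s(t)} where `s(t)` stacks
#' the radial-basis kernel values between `t` and the source control points.
#' The side conditions (columns of `W` sum to zero and are orthogonal to the
#' source coordinates) guarantee minimal bending energy.
#'
#' @slot affineOffset numeric length-2 vector `c`.
#' @slot affineMatrix 2 x 2 matrix `A`.
#' @slot weights N x 2 matrix `W` of kernel weights.
#' @slot sourcePoints the source [ControlPointSet-class].
#' @export
setClass("TPSCoefficients",
  representation(affineOffset = "numeric", affineMatrix = "matrix",
                 weights = "matrix", sourcePoints = "ControlPointSet"))

setValidity("TPSCoefficients", function(object) {
  if (length(object@affineOffset) != 2) return("affineOffset must have length 2")
  if (!all(dim(object@affineMatrix) == c(2, 2))) return("affineMatrix must be 2 x 2")
  W <- object@weights
  P <- controlPoints(object@sourcePoints)
  if (nrow(W) != nrow(P) || ncol(W) != 2) return("weights must be N x 2")
  tol <- 1e-6
  if (any(abs(colSums(W)) > tol)) return("side condition violated: colSums(W) != 0")
  if (any(abs(t(P) %*% W) > tol)) return("side condition violated: W not orthogonal to points")
  TRUE
})

#' Construct TPSCoefficients
#' @param affineOffset length-2 numeric.
#' @param affineMatrix 2 x 2 matrix.
#' @param weights N x 2 matrix.
#' @param sourcePoints a [ControlPointSet-class].
#' @export
tpsCoefficients <- function(affineOffset, affineMatrix, weights, sourcePoints)
  new("TPSCoefficients", affineOffset = as.numeric(affineOffset),
      affineMatrix = affineMatrix, weights = as.matrix(weights),
      sourcePoints = sourcePoints)

#' Identity TPS coefficients for a given source grid
#' @param sourcePoints a [ControlPointSet-class].
#' @export
identityTPS <- function(sourcePoints) {
  n <- nrow(controlPoints(sourcePoints))
  tpsCoefficients(c(0, 0), diag(2), matrix(0, n, 2), sourcePoints)
}

setMethod("show", "TPSCoefficients", function(object) {
  cat(sprintf("TPSCoefficients over %d control points; |c| = %.3g, ||W||_inf = %.3g\n",
              nrow(object@weights), sqrt(sum(object@affineOffset^2)),
              max(abs(object@weights))))
})

#' Co-registered phantom pair with known domain deformation
#'
#' @slot source domain-A [ImageSlice-class].
#' @slot targetAligned domain-B slice co-registered with the source.
#' @slot targetDeformed domain-B slice warped by the stored deformation.
#' @slot trueDeformation the exact [DisplacementField-class] applied.
#' @slot seed integer seed that generated the pair.
#' @export
setClass("PhantomPair",
  representation(source = "ImageSlice", targetAligned = "ImageSlice",
                 targetDeformed = "ImageSlice",
                 trueDeformation = "DisplacementField", seed = "integer"))

setValidity("PhantomPair", function(object) {
  if (!identical(dim(object@source@pixels), dim(object@targetAligned@pixels)))
    return("source and targetAligned must share geometry")
  TRUE
})

setMethod("show", "PhantomPair", function(object) {
  cat(sprintf("PhantomPair (seed %d): %d x %d, mean |deformation| = %.4g\n",
              object@seed, nrow(object@source@pixels), ncol(object@source@pixels),
              meanDisplacement(object@trueDeformation)))
})

#' Dataset manifest
#'
#' @slot entries data.frame with columns `file`, `domain`, `patient`,
#'   `slice`, `role`, `pair`, `offset`, `scale`.
#' @slot format `"nifti"`, `"tiff"` or `"png"`.
#' @slot root directory the file paths are relative to.
#' @export
setClass("DatasetManifest",
  representation(entries = "data.frame", format = "character", root = "character"))

setValidity("DatasetManifest", function(object) {
  need <- c("file", "domain", "patient", "slice", "role")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (!all(c("A", "B") %in% object@entries$domain))
    return("both domains must be non-empty")
  TRUE
})

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest (%s): %d entries under %s\n",
              object@format, nrow(object@entries), object@root))
})

#' Loss weighting coefficients
#'
#' Defaults follow the reference training setup:
#' `lambdaCyc = lambdaDicyc = 10`, `lambdaAlign = 0.9`.
#'
#' @slot lambdaCyc weight of the undeformed cycle-consistency term.
#' @slot lambdaDicyc weight of the deformation-invariant cycle term.
#' @slot lambdaAlign weight of the image-alignment term.
#' @export
setClass("LossWeights",
  representation(lambdaCyc = "numeric", lambdaDicyc = "numeric",
                 lambdaAlign = "numeric"))

setValidity("LossWeights", function(object) {
  if (any(c(object@lambdaCyc, object@lambdaDicyc, object@lambdaAlign) < 0))
    return("all loss weights must be nonnegative")
  TRUE
})

#' Construct LossWeights
#' @param lambdaCyc,lambdaDicyc,lambdaAlign nonnegative weights.
#' @export
lossWeights <- function(lambdaCyc = 10, lambdaDicyc = 10, lambdaAlign = 0.9)
  new("LossWeights", lambdaCyc = lambdaCyc, lambdaDicyc = lambdaDicyc,
      lambdaAlign = lambdaAlign)

#' Breakdown of the total training loss
#'
#' `total` always satisfies the exact identity
#' `total = ganAB + ganBA + lambdaAlign * align + lambdaCyc * cyc +
#'  lambdaDicyc * dicyc`.
#'
#' @slot ganAB,ganBA adversarial generator losses per direction.
#' @slot align image-alignment loss (undeformed outputs only).
#' @slot cyc undeformed cycle-consistency loss.
#' @slot dicyc deformation-invariant cycle-consistency loss.
#' @slot total weighted sum.
#' @slot weights the [LossWeights-class] used.
#' @export
setClass("LossBreakdown",
  representation(ganAB = "numeric", ganBA = "numeric", align = "numeric",
                 cyc = "numeric", dicyc = "numeric", total = "numeric",
                 weights = "LossWeights"))

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf(
    "LossBreakdown: total %.5g (ganAB %.4g, ganBA %.4g, align %.4g, cyc %.4g, dicyc %.4g)\n",
    object@total, object@ganAB, object@ganBA, object@align, object@cyc,
    object@dicyc))
})

#' Image-quality metrics report
#'
#' @slot mse mean squared error (squared normalized-intensity units).
#' @slot psnr peak signal-to-noise ratio in dB (`Inf` when `mse == 0`).
#' @slot ssim structural similarity index in `[-1, 1]`.
#' @slot nVoxels number of voxels the metrics were computed over.
#' @slot maskName optional mask label (`NA` when unmasked).
#' @export
setClass("MetricsReport",
  representation(mse = "numeric", psnr = "numeric", ssim = "numeric",
                 nVoxels = "integer", maskName = "character"))

setValidity("MetricsReport", function(object) {
  if (object@mse < 0) return("mse must be nonnegative")
  if (object@ssim > 1 + 1e-12) return("ssim cannot exceed 1")
  if (object@mse == 0 && is.finite(object@psnr))
    return("psnr must be infinite when mse is 0")
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: MSE %.4g, PSNR %s dB, SSIM %.4f (n = %d%s)\n",
              object@mse,
              if (is.finite(object@psnr)) sprintf("%.2f", object@psnr) else "Inf",
              object@ssim, object@nVoxels,
              if (is.na(object@maskName)) "" else paste0(", mask ", object@maskName)))
})

#' Result of one deformed generator pass
#'
#' Holds the two synthesized images produced by one generator direction: the
#' undeformed output aligned with the source, and the deformed output carrying
#' the estimated domain-specific deformation, together with the deformation
#' fields used.
#'
#' @slot undeformed synthesized [ImageSlice-class] with deformation bypassed.
#' @slot deformed synthesized slice with local and global deformation applied.
#' @slot localFields list of per-layer [DisplacementField-class] offsets.
#' @slot globalField dense global [DisplacementField-class] (latent resolution).
#' @slot controlPts predicted target [ControlPointSet-class].
#' @export
setClass("DualSynthesis",
  representation(undeformed = "ImageSlice", deformed = "ImageSlice",
                 localFields = "list", globalField = "DisplacementField",
                 controlPts = "ControlPointSet"))

setMethod("show", "DualSynthesis", function(object) {
  cat(sprintf("DualSynthesis: %d x %d, %d local fields, mean |global| = %.4g\n",
              nrow(object@undeformed@pixels), ncol(object@undeformed@pixels),
              length(object@localFields), meanDisplacement(object@globalField)))
})
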