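# Thin-plate-spline machinery for the global deformation model: radial
# kernel, coefficient fitting with side conditions, dense displacement
# evaluation, bilinear resampling and field composition. All coordinates are
# normalized to [-1, 1] with pixel centers at the interval ends
# (align-corners convention).

#' Thin-plate-spline radial basis kernel
#'
#' \eqn{\delta(r) = r^2 \log r} with the continuity convention
#' \eqn{\delta(0) = 0}. The natural logarithm is used; any other base only
#' rescales the fitted weights.
#'
#' @param r nonnegative radius (vectorized).
#' @return Kernel values, same shape as `r`.
#' @examples
#' tpsKernel(1)   # 0
#' tpsKernel(2)   # 4 * log(2)
#' @export
tpsKernel <- function(r) {
  if (any(r < 0)) stop("tpsKernel: radius must be nonnegative")
  out <- numeric(length(r))
  nz <- r > 0
  out[nz] <- r[nz]^2 * log(r[nz])
  if (!is.null(dim(r))) dim(out) <- dim(r)
  out
}

#' Regular square grid of control points
#'
#' `n^2` points evenly spaced over \eqn{[-1, 1]^2} inclusive, ordered with the
#' second (y) coordinate varying fastest.
#'
#' @param n grid side (>= 2); the default 6 gives the standard 36-point grid.
#' @return A [ControlPointSet-class] with layout `"regular-grid"`.
#' @export
regularControlGrid <- function(n = 6) {
  if (n < 2) stop("regularControlGrid: n must be at least 2")
  g <- seq(-1, 1, length.out = n)
  pts <- cbind(x = rep(g, each = n), y = rep(g, times = n))
  controlPointSet(unname(pts), layout = "regular-grid")
}

# pairwise kernel matrix between two point sets (rows = query, cols = source)
tps_kernel_matrix <- function(query, source) {
  dx <- outer(query[, 1], source[, 1], "-")
  dy <- outer(query[, 2], source[, 2], "-")
  tpsKernel(sqrt(dx^2 + dy^2))
}

tps_system <- function(P, regularization = 0) {
  n <- nrow(P)
  K <- tps_kernel_matrix(P, P)
  if (regularization > 0) K <- K + diag(regularization, n)
  Pa <- cbind(1, P)
  rbind(cbind(K, Pa), cbind(t(Pa), matrix(0, 3, 3)))
}

#' Fit a thin-plate spline between two control point sets
#'
#' Solves the standard TPS linear system with side conditions so that the
#' fitted map interpolates every source point onto its target exactly while
#' minimizing bending energy. Targets related to the sources by an exact
#' affine map therefore yield zero kernel weights.
#'
#' @param source,target [ControlPointSet-class] objects of equal size.
#' @param regularization optional Tikhonov term added to the kernel block
#'   (default 0); useful for near-degenerate configurations.
#' @return A [TPSCoefficients-class] object.
#' @export
fitTPS <- function(source, target, regularization = 0) {
  Ps <- controlPoints(source)
  Pt <- controlPoints(target)
  if (!all(dim(Ps) == dim(Pt)))
    stop("fitTPS: source and target must have the same number of points")
  if (identical(Ps, Pt)) return(identityTPS(source))
  n <- nrow(Ps)
  L <- tps_system(Ps, regularization)
  rhs <- rbind(Pt, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs), error = function(e)
    stop("fitTPS: degenerate (collinear or duplicated) source points; ",
         "consider regularization > 0", call. = FALSE))
  W <- coef[seq_len(n), , drop = FALSE]
  c0 <- coef[n + 1, ]
  A <- t(coef[n + 2:3, , drop = FALSE])
  tpsCoefficients(c0, A, W, source)
}

#' Evaluate a fitted TPS map at arbitrary points
#'
#' @param coeffs a [TPSCoefficients-class].
#' @param pts M x 2 matrix of normalized coordinates.
#' @return M x 2 matrix of mapped coordinates \eqn{\Phi(t)}.
#' @export
evalTPS <- function(coeffs, pts) {
  pts <- as.matrix(pts)
  Ps <- controlPoints(coeffs@sourcePoints)
  S <- tps_kernel_matrix(pts, Ps)
  sweep(pts %*% t(coeffs@affineMatrix) + S %*% coeffs@weights,
        2, coeffs@affineOffset, "+")
}

#' Identity sampling grid in normalized coordinates
#'
#' @param H,W spatial dimensions.
#' @return H x W x 2 array of absolute coordinates (channel 1 = x over the
#'   width, channel 2 = y over the height), each spanning `[-1, 1]`.
#' @export
identityGrid <- function(H, W) {
  xs <- if (W > 1) seq(-1, 1, length.out = W) else 0
  ys <- if (H > 1) seq(-1, 1, length.out = H) else 0
  g <- array(0, dim = c(H, W, 2))
  g[, , 1] <- matrix(xs, H, W, byrow = TRUE)
  g[, , 2] <- matrix(ys, H, W)
  g
}

#' Dense displacement field of a fitted TPS
#'
#' Evaluates \eqn{\Phi(t) - t} on the dense normalized pixel grid of the
#' requested shape.
#'
#' @param coeffs a [TPSCoefficients-class].
#' @param shape integer vector `(H, W)`.
#' @return A [DisplacementField-class].
#' @export
tpsDisplacement <- function(coeffs, shape) {
  H <- shape[1]; W <- shape[2]
  grid <- identityGrid(H, W)
  pts <- cbind(as.vector(grid[, , 1]), as.vector(grid[, , 2]))
  if (all(coeffs@weights == 0) &&
      identical(unname(coeffs@affineMatrix), diag(2)) &&
      all(coeffs@affineOffset == 0))
    return(zeroField(H, W))
  mapped <- evalTPS(coeffs, pts)
  off <- array(0, dim = c(H, W, 2))
  off[, , 1] <- matrix(mapped[, 1], H, W) - grid[, , 1]
  off[, , 2] <- matrix(mapped[, 2], H, W) - grid[, , 2]
  displacementField(off)
}

# Linear operator mapping target control points to the dense TPS-mapped
# coordinates: dense = M %*% targetPoints (one column per coordinate). Used
# where the dense field must stay differentiable in the predicted points.
tps_linear_operator <- function(sourcePoints, shape) {
  Ps <- controlPoints(sourcePoints)
  n <- nrow(Ps)
  H <- shape[1]; W <- shape[2]
  key <- paste0("tpslin_", n, "_", H, "_", W, "_",
                paste0(signif(Ps[c(1, n), ], 8), collapse = ","))
  cached <- .ad[[key]]
  if (!is.null(cached)) return(cached)
  L <- tps_system(Ps)
  Linv <- solve(L)
  grid <- identityGrid(H, W)
  pts <- cbind(as.vector(grid[, , 1]), as.vector(grid[, , 2]))
  E <- cbind(tps_kernel_matrix(pts, Ps), 1, pts)  # HW x (n+3)
  M <- E %*% Linv[, seq_len(n), drop = FALSE]     # HW x n
  .ad[[key]] <- M
  M
}

#' Resample a grid of values through a displacement field
#'
#' Bilinear interpolation at `identity + field` locations in normalized
#' coordinates. All channels are sampled with the same field. A field that is
#' exactly zero returns the input unchanged, bit for bit.
#'
#' @param x numeric matrix (H x W) or array (H x W x C).
#' @param field a [DisplacementField-class] whose spatial shape matches `x`.
#' @param padding out-of-bounds handling: `"border"` (clamp, default) or
#'   `"zeros"`.
#' @return Same shape and type as `x`.
#' @export
resampleGrid <- function(x, field, padding = c("border", "zeros")) {
  padding <- match.arg(padding)
  off <- fieldOffsets(field)
  was_matrix <- is.matrix(x)
  xa <- if (was_matrix) array(x, dim = c(dim(x), 1)) else x
  d <- dim(xa)
  if (!all(dim(off)[1:2] == d[1:2]))
    stop("resampleGrid: field shape does not match input")
  if (all(off == 0)) return(x)
  grid <- identityGrid(d[1], d[2]) + off
  y <- cpp_grid_sample_fw(xa, grid, if (padding == "border") 1L else 0L)
  if (was_matrix) matrix(y, d[1], d[2]) else y
}

#' @describeIn resampleGrid Resample an [ImageSlice-class]; returns a slice.
#' @param slice an `ImageSlice`.
#' @export
resampleSlice <- function(slice, field, padding = "border") {
  imageSlice(resampleGrid(pixels(slice), field, padding),
             domain = slice@domain, spacing = slice@spacing, id = slice@id)
}

#' Compose two displacement fields
#'
#' Returns the single field equivalent to resampling through `first` and then
#' through `second`: since resampling is a pull-back, the composed field is
#' `second` plus `first` sampled at the `second`-displaced locations, so that
#' `resampleGrid(x, composeFields(f, g))` matches
#' `resampleGrid(resampleGrid(x, f), g)` up to interpolation error.
#'
#' @param first,second [DisplacementField-class] objects of the same shape.
#' @return A [DisplacementField-class].
#' @export
composeFields <- function(first, second) {
  o1 <- fieldOffsets(first)
  o2 <- fieldOffsets(second)
  if (!all(dim(o1) == dim(o2))) stop("composeFields: shape mismatch")
  if (all(o2 == 0)) return(first)
  if (all(o1 == 0)) return(second)
  d <- dim(o1)
  grid <- identityGrid(d[1], d[2]) + o2
  sampled <- cpp_grid_sample_fw(o1, grid, 1L)
  displacementField(o2 + sampled)
}

#' Write a displacement field to NIfTI with a YAML sidecar
#'
#' The two offset channels are stored as a `H x W x 1 x 2` NIfTI volume; the
#' sidecar records the coordinate convention.
#'
#' @param field a [DisplacementField-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @export
saveField <- function(field, path) {
  off <- fieldOffsets(field)
  arr <- array(off, dim = c(dim(off)[1], dim(off)[2], 1, 2))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  yaml::write_yaml(
    list(kind = "displacement_field",
         convention = "normalized [-1,1], align-corners, additive to identity grid",
         channels = c("x (width)", "y (height)")),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read a displacement field written by [saveField()]
#' @param path path to the NIfTI file.
#' @return A [DisplacementField-class].
#' @export
loadField <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  displacementField(array(arr, dim = c(d[1], d[2], 2)))
}
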