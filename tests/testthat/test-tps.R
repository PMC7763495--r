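# Thin-plate-spline machinery: kernel convention, control grids, fitting
# with side conditions, dense field evaluation, resampling and composition.

test_that("radial kernel follows r^2 log r with delta(0) = 0", {
  expect_identical(tpsKernel(0), 0)
  expect_identical(tpsKernel(1), 0)
  expect_equal(tpsKernel(2), 4 * log(2))
  expect_equal(tpsKernel(c(0, 1, 2, 3)), c(0, 0, 4 * log(2), 9 * log(3)))
  expect_error(tpsKernel(-1), "nonnegative")
})

test_that("regular control grids span [-1,1]^2 inclusively", {
  g2 <- controlPoints(regularControlGrid(2))
  expect_equal(g2, cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1)))
  expect_equal(nrow(controlPoints(regularControlGrid(6))), 36)
  g3 <- controlPoints(regularControlGrid(3))
  expect_equal(g3[5, ], c(0, 0))
  expect_error(regularControlGrid(1), "at least 2")
})

test_that("TPS fitting is interpolating, affine-exact and side-conditioned", {
  g <- regularControlGrid(6)
  # identity
  cf0 <- fitTPS(g, g)
  expect_equal(cf0@affineOffset, c(0, 0))
  expect_equal(cf0@affineMatrix, diag(2))
  expect_true(all(cf0@weights == 0))
  # pure translation
  tr <- controlPointSet(sweep(controlPoints(g) * 0.9, 2, c(0.05, 0), "+"))
  cft <- fitTPS(controlPointSet(controlPoints(g) * 0.9), tr)
  expect_equal(cft@affineOffset, c(0.05, 0), tolerance = 1e-10)
  expect_equal(cft@affineMatrix, diag(2), tolerance = 1e-10)
  expect_lt(max(abs(cft@weights)), 1e-8)
  # general affine target: zero bending weights
  A <- matrix(c(0.8, 0.1, -0.05, 0.9), 2, 2)
  tgt <- controlPoints(g) %*% t(A)
  cfa <- fitTPS(g, controlPointSet(tgt))
  expect_lt(max(abs(cfa@weights)), 1e-8)
  expect_equal(cfa@affineMatrix, A, tolerance = 1e-9)
  # one moved point: exact interpolation at every control point
  tgt2 <- controlPoints(g)
  tgt2[14, ] <- tgt2[14, ] + c(0.05, -0.02)
  cf2 <- fitTPS(g, controlPointSet(tgt2))
  expect_lt(max(abs(evalTPS(cf2, controlPoints(g)) - tgt2)), 1e-6)
  # side conditions
  P <- controlPoints(g)
  expect_lt(max(abs(colSums(cf2@weights))), 1e-8)
  expect_lt(max(abs(t(P) %*% cf2@weights)), 1e-8)
  # degenerate (collinear) sources fail without regularization
  lin <- controlPointSet(cbind(seq(-0.9, 0.9, length.out = 5),
                               seq(-0.9, 0.9, length.out = 5)))
  lin2 <- controlPointSet(controlPoints(lin) + 0.01)
  expect_error(fitTPS(lin, lin2), "degenerate")
})

test_that("dense displacement equals pointwise evaluation of the fitted map", {
  g <- regularControlGrid(6)
  expect_true(all(fieldOffsets(tpsDisplacement(identityTPS(g), c(10, 12))) == 0))
  # pure affine scaling: field is 0.1 * t everywhere
  cfa <- tpsCoefficients(c(0, 0), 1.1 * diag(2), matrix(0, 36, 2), g)
  fld <- fieldOffsets(tpsDisplacement(cfa, c(9, 9)))
  idg <- identityGrid(9, 9)
  expect_equal(fld, 0.1 * idg, tolerance = 1e-12)
  # arbitrary coefficients: probe pixels against direct evaluation
  set.seed(21)
  tgt <- controlPoints(g) + matrix(rnorm(72, sd = 0.04), 36, 2)
  cf <- fitTPS(g, controlPointSet(pmin(pmax(tgt, -1), 1)))
  fld2 <- fieldOffsets(tpsDisplacement(cf, c(16, 16)))
  idg2 <- identityGrid(16, 16)
  for (probe in list(c(1, 1), c(7, 3), c(16, 16), c(5, 12))) {
    p <- cbind(idg2[probe[1], probe[2], 1], idg2[probe[1], probe[2], 2])
    direct <- evalTPS(cf, p) - p
    expect_equal(c(fld2[probe[1], probe[2], 1], fld2[probe[1], probe[2], 2]),
                 as.vector(direct), tolerance = 1e-12)
  }
})

test_that("resampling: identity is bit-exact, constants invariant, impulse shifts", {
  set.seed(22)
  x <- matrix(rnorm(20 * 24), 20, 24)
  expect_identical(resampleGrid(x, zeroField(20, 24)), x)
  cst <- matrix(3.7, 16, 16)
  fld <- displacementField(array(rnorm(16 * 16 * 2, sd = 0.2), c(16, 16, 2)))
  expect_equal(resampleGrid(cst, fld, "border"), cst, tolerance = 1e-12)
  # unit impulse moved one column by a field of 2/(W-1) in x
  W <- 16
  imp <- matrix(0, 16, W); imp[8, 9] <- 1
  shift <- constant_field(16, W, 2 / (W - 1), 0)
  out <- resampleGrid(imp, shift, "border")
  oracle <- oracle_bilinear(array(imp, c(16, W, 1)),
                            identityGrid(16, W) + fieldOffsets(shift))
  expect_equal(out, oracle[, , 1], tolerance = 1e-12)
  expect_equal(out[8, 8], 1)   # content moves against the sampling shift
  expect_equal(sum(out), 1)
})

test_that("field composition matches sequential resampling", {
  z <- zeroField(12, 12)
  set.seed(23)
  f <- displacementField(array(rnorm(288, sd = 0.05), c(12, 12, 2)))
  expect_identical(fieldOffsets(composeFields(z, f)), fieldOffsets(f))
  expect_identical(fieldOffsets(composeFields(f, z)), fieldOffsets(f))
  u <- constant_field(12, 12, 0.1, -0.05)
  v <- constant_field(12, 12, 0.07, 0.12)
  expect_equal(fieldOffsets(composeFields(u, v)),
               fieldOffsets(u) + fieldOffsets(v), tolerance = 1e-12)
  # random smooth fields (tapered to zero at the border so that border
  # clamping does not enter): composition matches sequential resampling
  H <- 64
  g <- identityGrid(H, H)
  img <- sin(pi / 2 * g[, , 1]) * cos(pi / 2 * g[, , 2]) +
    0.5 * sin(pi / 2 * (g[, , 1] + g[, , 2]))
  taper <- sin(pi * (g[, , 1] + 1) / 2)^2 * sin(pi * (g[, , 2] + 1) / 2)^2
  set.seed(23)
  mk <- function() {
    o <- array(0, c(H, H, 2))
    for (k in 1:2)
      o[, , k] <- 0.03 * sin(pi / 2 * g[, , 1] + runif(1, 0, 6)) *
        cos(pi / 2 * g[, , 2] + runif(1, 0, 6)) * taper
    displacementField(o)
  }
  f1 <- mk(); f2 <- mk()
  seq2 <- resampleGrid(resampleGrid(img, f1), f2)
  comp <- resampleGrid(img, composeFields(f1, f2))
  expect_lt(max(abs(seq2 - comp)), 1e-3)
})

test_that("fields round-trip through NIfTI serialization", {
  set.seed(24)
  f <- displacementField(array(rnorm(2 * 18 * 20, sd = 0.1), c(18, 20, 2)))
  path <- tempfile(fileext = ".nii.gz")
  saveField(f, path)
  g <- loadField(path)
  expect_equal(fieldOffsets(g), fieldOffsets(f), tolerance = 1e-7)
  expect_true(file.exists(paste0(path, ".yaml")))
})
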