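# Loss terms: closed-form cases, independent elementwise oracles, the NMI
# estimator's limiting values, and the structural separation between the
# alignment loss (undeformed pass) and the adversarial losses (deformed pass).

test_that("least-squares adversarial losses match their closed forms", {
  ones <- matrix(1, 4, 4); zeros <- matrix(0, 4, 4)
  expect_equal(lsganDiscriminatorLoss(ones, zeros), 0)
  expect_equal(lsganDiscriminatorLoss(zeros, ones), 1)
  expect_equal(lsganGeneratorLoss(ones), 0)
  expect_equal(lsganGeneratorLoss(zeros), 1)
  expect_equal(lsganGeneratorLoss(matrix(0.5, 3, 3)), 0.25)
  set.seed(51)
  r <- matrix(runif(25), 5); f <- matrix(runif(25), 5)
  expect_equal(lsganDiscriminatorLoss(r, f),
               mean((r - 1)^2) / 2 + mean(f^2) / 2)
  expect_equal(lsganGeneratorLoss(f), mean((f - 1)^2))
  expect_error(lsganDiscriminatorLoss(r, matrix(0, 2, 2)), "mismatch")
  # logistic form behind the flag
  expect_equal(lsganGeneratorLoss(matrix(exp(-1), 2, 2), form = "log"), 1,
               tolerance = 1e-9)
})

test_that("NMI limits: self-dependence, independence, monotone invariance, constants", {
  set.seed(52)
  x <- matrix(runif(128 * 128), 128)
  expect_equal(normalizedMutualInformation(x, x), 1)
  y <- matrix(runif(128 * 128), 128)
  expect_lt(normalizedMutualInformation(x, y, bins = 64), 0.05)
  # strictly monotone map, rank binning: identical bin partition, NMI = 1
  expect_equal(normalizedMutualInformation(x, exp(3 * x), binning = "rank"), 1)
  expect_warning(v <- normalizedMutualInformation(matrix(1, 32, 32), x[1:32, 1:32]),
                 "constant")
  expect_equal(v, 0)
  expect_error(normalizedMutualInformation(x, y[1:64, 1:64]), "same shape")
  # soft mode is bounded and high for identical images
  s <- normalizedMutualInformation(x[1:32, 1:32], x[1:32, 1:32], mode = "soft")
  expect_gt(s, normalizedMutualInformation(x[1:32, 1:32], y[1:32, 1:32],
                                           mode = "soft"))
})

test_that("alignment loss arithmetic, bounds and measure plumbing", {
  x <- matrix(runif(256), 16)
  vals <- c(0.8, 0.6); i <- 0
  meter <- function(a, b) { i <<- i + 1; vals[i] }
  expect_equal(alignmentLoss(x, x, x, x, measure = meter), 2 - 0.8 - 0.6)
  expect_equal(alignmentLoss(x, x, x, x,
                             measure = function(a, b) 1), 0)
  expect_equal(alignmentLoss(x, x, x, x,
                             measure = function(a, b) 0), 2)
  expect_error(alignmentLoss(x, x, x, x, measure = function(a, b) 1.5),
               "outside")
  # registry plugins are selectable
  registerAlignmentMeasure("half", function(a, b) 0.5)
  expect_equal(alignmentLoss(x, x, x, x, measure = "plugin:half"), 1)
  expect_error(alignmentMeasure("plugin:nothere"), "no registered")
  # NMI measure: linear maps preserve the equal-width bin partition, so
  # perfectly dependent synthesized images give zero loss
  expect_equal(alignmentLoss(x, 2 * x + 1, x, 0.5 * x - 2, measure = "nmi"), 0,
               tolerance = 1e-9)
})

test_that("GCC: self and inverted images correlate fully; oracle agreement", {
  set.seed(53)
  x <- matrix(runif(32 * 32), 32)
  expect_equal(gccAlignment(x, x), 1, tolerance = 1e-6)
  expect_equal(gccAlignment(x, 1 - x), 1, tolerance = 1e-6)
  expect_warning(gccAlignment(matrix(0, 32, 32), x), "zero-gradient")
  # independent oracle: direct correlation of central-difference gradients
  y <- matrix(runif(32 * 32), 32)
  cd <- function(m, axis) {
    p <- matrix(0, nrow(m), ncol(m))
    if (axis == "x") p[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / 2
    else p[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / 2
    p
  }
  # reflect padding makes the boundary derivative zero, as in cd()
  gx1 <- cd(x, "x"); gx2 <- cd(y, "x")
  gy1 <- cd(x, "y"); gy2 <- cd(y, "y")
  pop_cor <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    mean(a * b) / (sqrt(mean(a^2)) * sqrt(mean(b^2)) + 1e-8)
  }
  want <- (abs(pop_cor(gx1, gx2)) + abs(pop_cor(gy1, gy2))) / 2
  expect_equal(gccAlignment(x, y), want, tolerance = 1e-10)
})

test_that("cycle losses: identity, constant-shift closed form, L1 oracle", {
  set.seed(54)
  x <- matrix(rnorm(64), 8); y <- matrix(rnorm(64), 8)
  expect_equal(cycleLoss(x, x, y, y), 0)
  c0 <- 0.3   # each direction adds c per pass: round trip is off by 2c
  expect_equal(cycleLoss(x, x + 2 * c0, y, y + 2 * c0), 2 * abs(2 * c0))
  a <- matrix(rnorm(64), 8); b <- matrix(rnorm(64), 8)
  expect_equal(cycleLoss(x, a, y, b),
               mean(abs(x - a)) + mean(abs(y - b)))
  expect_error(cycleLoss(x, a[1:4, ], y, b), "mismatch")
  expect_equal(dicycLoss(x, a, y, b), cycleLoss(x, a, y, b))
})

test_that("deformed round trip through a field and its numerical inverse is small", {
  H <- 64
  g <- identityGrid(H, H)
  img <- sin(pi / 2 * g[, , 1]) * cos(pi / 2 * g[, , 2])
  taper <- sin(pi * (g[, , 1] + 1) / 2)^2 * sin(pi * (g[, , 2] + 1) / 2)^2
  o <- array(0, c(H, H, 2))
  o[, , 1] <- 0.05 * sin(pi / 2 * g[, , 2]) * taper
  o[, , 2] <- 0.05 * cos(pi / 2 * g[, , 1]) * taper
  f <- displacementField(o)
  # fixed-point inversion of the displacement field
  inv <- o
  for (k in 1:30) {
    s <- ns$cpp_grid_sample_fw(o, g + inv, 1L)
    inv <- -s
  }
  finv <- displacementField(inv)
  cycled <- resampleGrid(resampleGrid(img, f), finv)
  expect_lt(dicycLoss(img, cycled, img, cycled) / 2, 1e-2)
})

test_that("total loss keeps the exact weighted-sum identity", {
  w <- lossWeights()   # (10, 10, 0.9)
  lb <- totalLoss(1, 1, 1, 1, 1, w)
  expect_identical(lb@total, 1 + 1 + 0.9 + 10 + 10)
  set.seed(55)
  p <- runif(5)
  lb2 <- totalLoss(p[1], p[2], p[3], p[4], p[5], w)
  expect_identical(lb2@total,
                   p[1] + p[2] + 0.9 * p[3] + 10 * p[4] + 10 * p[5])
  # degenerations
  lb3 <- totalLoss(p[1], p[2], p[3], p[4], p[5],
                   lossWeights(lambdaAlign = 0))
  expect_identical(lb3@total, p[1] + p[2] + 10 * p[4] + 10 * p[5])
  expect_error(totalLoss(1, NaN, 1, 1, 1), "ganBA")
  expect_error(lossWeights(lambdaCyc = -1), "nonnegative")
})

test_that("alignment loss has exactly zero gradient in all deformation parameters", {
  set.seed(56)
  cfg <- tiny_train_config()
  st <- newTrainState(cfg)
  xA <- ns$ad_tensor(array(rnorm(32 * 32), c(32, 32, 1)))
  xB <- ns$ad_tensor(array(rnorm(32 * 32), c(32, 32, 1)))
  xhatB <- st$genAB$decode(st$genAB$encode(xA, offsets = FALSE)$latent)
  xhatA <- st$genBA$decode(st$genBA$encode(xB, offsets = FALSE)$latent)
  align <- ns$ad_sub(2, ns$ad_add(ns$nmi_soft_node(xA, xhatB),
                                  ns$nmi_soft_node(xB, xhatA)))
  ns$ad_zero_grad(ns$all_state_params(st))
  ns$ad_backward(align)
  deform_params <- c(st$transAB$params, st$transBA$params,
                     st$genAB$offset_params, st$genBA$offset_params)
  for (p in deform_params) expect_null(p$grad)
  # ... while the synthesis parameters do receive gradient
  expect_false(is.null(st$genAB$synth_params[[1]]$grad))
})

test_that("adversarial loss ignores the undeformed output and feels the deformation", {
  set.seed(57)
  cfg <- tiny_train_config()
  st <- newTrainState(cfg)
  # make the deformation nontrivial
  randomize_params(c(st$transAB$params, st$transBA$params), sd = 0.3)
  xA <- ns$ad_tensor(array(rnorm(32 * 32), c(32, 32, 1)))
  xB <- ns$ad_tensor(array(rnorm(32 * 32), c(32, 32, 1)))
  und <- st$genAB$decode(st$genAB$encode(xA, offsets = FALSE)$latent)
  dp <- ns$deformed_passes(st, xA, xB)
  gan <- ns$lsgan_g_node(st$dB$forward(dp$xTB))
  ns$ad_zero_grad(ns$all_state_params(st))
  ns$ad_backward(gan)
  expect_null(und$grad)                                    # undeformed pass untouched
  expect_false(is.null(st$transAB$params[[1]]$grad))       # deformation path live
  # and perturbing the transformer changes the adversarial loss but not the
  # alignment loss computed from the undeformed outputs
  align_val <- function() {
    u <- st$genAB$decode(st$genAB$encode(xA, offsets = FALSE)$latent)
    ns$vof(ns$nmi_soft_node(xA, u))
  }
  gan_val <- function() {
    dp <- ns$deformed_passes(st, xA, xB)
    ns$vof(ns$lsgan_g_node(st$dB$forward(dp$xTB)))
  }
  v1a <- align_val(); v1g <- gan_val()
  st$transAB$params[[length(st$transAB$params) - 1]]$value[] <-
    st$transAB$params[[length(st$transAB$params) - 1]]$value + 0.5
  expect_identical(align_val(), v1a)
  expect_false(isTRUE(all.equal(gan_val(), v1g)))
})
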