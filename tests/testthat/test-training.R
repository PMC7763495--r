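# Training loop: schedule, augmentation, sampling, the E/M parameter-freeze
# contracts, determinism and checkpoint round trips.

test_that("learning-rate schedule: fixed phase then linear decay to zero", {
  cfg <- trainConfig()
  expect_equal(learningRate(0, cfg), 2e-4)
  expect_equal(learningRate(99, cfg), 2e-4)
  expect_equal(learningRate(150, cfg), 1e-4)
  expect_equal(learningRate(199, cfg), 2e-6)
  expect_error(learningRate(200, cfg), "range")
  expect_error(learningRate(-1, cfg), "range")
})

test_that("affine augmentation: identity, flip involution, rotation oracle", {
  set.seed(61)
  sl <- imageSlice(matrix(rnorm(32 * 32), 32))
  zero <- list(translation = 0, rotation = 0, scale = 0, shear = 0, flip = 0)
  expect_identical(pixels(augmentAffine(sl, 5, zero)), pixels(sl))
  flipr <- modifyList(zero, list(flip = 1))
  once <- augmentAffine(sl, 5, flipr)
  expect_identical(pixels(once), pixels(sl)[, 32:1])
  expect_identical(pixels(augmentAffine(once, 6, flipr)), pixels(sl))
  # pure rotation equals resampling through the closed-form affine field
  rotr <- modifyList(zero, list(rotation = 30))
  got <- augmentAffine(sl, 9, rotr)
  theta <- ns$with_local_seed(9, {
    runif(1, 0, 0); runif(1, 0, 0)   # translation draws (zero range)
    runif(1, -30, 30) * pi / 180
  })
  g <- identityGrid(32, 32)
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  pts <- cbind(as.vector(g[, , 1]), as.vector(g[, , 2])) %*% t(R)
  off <- array(0, c(32, 32, 2))
  off[, , 1] <- matrix(pts[, 1], 32, 32) - g[, , 1]
  off[, , 2] <- matrix(pts[, 2], 32, 32) - g[, , 2]
  want <- resampleGrid(pixels(sl), displacementField(off), "border")
  expect_equal(pixels(got), want, tolerance = 1e-12)
})

test_that("minibatch sampling is deterministic and respects the patient contract", {
  pairs <- generatePhantomDataset(6, seed = 3, size = c(32, 32))
  ds <- phantomTrainingSet(pairs)
  b1 <- sampleMinibatch(ds, "random-patient-slice", seed = 11)
  b2 <- sampleMinibatch(ds, "random-patient-slice", seed = 11)
  expect_identical(b1$indexA, b2$indexA)
  expect_identical(b1$indexB, b2$indexB)
  b3 <- sampleMinibatch(ds, "same-patient-random-slice", seed = 12)
  expect_identical(ds$patientA[b3$indexA], ds$patientB[b3$indexB])
  expect_error(sampleMinibatch(list(A = list(), B = ds$B), seed = 1),
               "non-empty")
})

test_that("patient selection frequencies are uniform over many draws", {
  pairs <- generatePhantomDataset(5, seed = 4, size = c(32, 32))
  ds <- phantomTrainingSet(pairs)
  n <- 6000
  counts <- integer(5)
  for (s in seq_len(n)) {
    b <- sampleMinibatch(ds, "random-patient-slice", seed = s)
    counts[b$indexA] <- counts[b$indexA] + 1L
  }
  expected <- n / 5
  sdev <- sqrt(n * (1 / 5) * (4 / 5))
  expect_true(all(abs(counts - expected) <= 3 * sdev))
})

test_that("E-step updates only the global transformer parameters", {
  set.seed(62)
  cfg <- tiny_train_config()
  st <- newTrainState(cfg)
  batch <- list(A = matrix(rnorm(32 * 32), 32), B = matrix(rnorm(32 * 32), 32))
  frozen <- ns$params_values(c(st$genAB$params, st$genBA$params,
                               st$dA$params, st$dB$params))
  before_t <- ns$params_values(c(st$transAB$params, st$transBA$params))
  eStep(st, batch)
  after <- ns$params_values(c(st$genAB$params, st$genBA$params,
                              st$dA$params, st$dB$params))
  expect_identical(after, frozen)       # bitwise: synthesis and D untouched
  after_t <- ns$params_values(c(st$transAB$params, st$transBA$params))
  expect_false(identical(after_t, before_t))
  # zero transformer learning rate leaves everything unchanged
  st$optT$lr <- 0
  snap <- ns$params_values(ns$all_state_params(st))
  eStep(st, batch)
  expect_identical(ns$params_values(ns$all_state_params(st)), snap)
})

test_that("M-step: zero lr reports losses without changing parameters; identity holds", {
  set.seed(63)
  cfg <- tiny_train_config()
  st <- newTrainState(cfg)
  st$optG$lr <- 0; st$optD$lr <- 0
  batch <- list(A = matrix(rnorm(32 * 32), 32), B = matrix(rnorm(32 * 32), 32))
  snap <- ns$params_values(ns$all_state_params(st))
  res <- mStep(st, batch)
  expect_identical(ns$params_values(ns$all_state_params(st)), snap)
  bd <- res$breakdown
  w <- cfg$weights
  expect_identical(bd@total, bd@ganAB + bd@ganBA + w@lambdaAlign * bd@align +
                     w@lambdaCyc * bd@cyc + w@lambdaDicyc * bd@dicyc)
  expect_true(all(c(bd@ganAB, bd@ganBA, bd@align, bd@cyc, bd@dicyc) >= 0))
})

test_that("training is deterministic and checkpoints restore it bit-compatibly", {
  pairs <- generatePhantomDataset(2, seed = 8, size = c(32, 32))
  ds <- phantomTrainingSet(pairs)
  run_losses <- function(state, n, seed) {
    set.seed(seed)
    vapply(seq_len(n), function(i) {
      mb <- sampleMinibatch(ds, seed = sample.int(1e6, 1))
      batch <- list(A = pixels(mb$A[[1]]), B = pixels(mb$B[[1]]))
      eStep(state, batch)
      mStep(state, batch)$breakdown@total
    }, 0)
  }
  st1 <- newTrainState(tiny_train_config())
  st2 <- newTrainState(tiny_train_config())
  l1 <- run_losses(st1, 3, 99)
  l2 <- run_losses(st2, 3, 99)
  expect_identical(l1, l2)
  ck <- tempfile(fileext = ".bin")
  saveCheckpoint(st1, ck)
  cont1 <- run_losses(st1, 3, 100)
  st3 <- loadCheckpoint(ck)
  cont2 <- run_losses(st3, 3, 100)
  expect_identical(cont1, cont2)
})

test_that("the training driver respects epoch bookkeeping and degenerate configs", {
  pairs <- generatePhantomDataset(2, seed = 9, size = c(32, 32))
  ds <- phantomTrainingSet(pairs)
  cfg0 <- tiny_train_config(epochsFixed = 0L, epochsDecay = 0L)
  st0 <- trainDicyc(cfg0, ds)
  expect_equal(st0$iteration, 0L)
  expect_equal(nrow(lossHistory(st0)), 0)
  cfg <- tiny_train_config(epochsFixed = 2L, epochsDecay = 0L,
                           iterationsPerEpoch = 3L, mode = "cyclegan+align")
  out <- file.path(tempdir(), "trainrun")
  st <- trainDicyc(cfg, ds, outDir = out)
  h <- lossHistory(st)
  expect_equal(nrow(h), 2 * 3)
  expect_true(all(h$dicyc == 0))       # deformation modules disabled
  expect_true(file.exists(file.path(out, "loss_log.csv")))
  expect_true(file.exists(file.path(out, "epoch_002.bin")))
})
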