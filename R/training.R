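# Expectation-maximization training. Each iteration runs an E-step that
# updates only the global transformer parameters (driven by the adversarial
# and deformation-invariant cycle terms evaluated on the deformed passes) and
# an M-step that runs both forward passes per direction, assembles the full
# weighted loss and updates the synthesis parameters (including the local
# offset convolutions) and the discriminators. A mode switch degenerates the
# model to a vanilla cycle-consistency GAN (optionally with the alignment
# loss) for ablation parity.

#' Training configuration
#'
#' Defaults follow the reference setup: Adam (betas 0.5/0.999) with learning
#' rate 2e-4 fixed for 100 epochs then linearly decayed to 0 over 100 more,
#' 6000 iterations per epoch, loss weights (10, 10, 0.9), a 50-image
#' historical fake pool, batch size 1, and a two-phase early-stopping rule
#' (tolerances 10 and 20 epochs). Reduced desk-scale configurations (smaller
#' images, fewer iterations, narrower networks) are first-class.
#'
#' @param lr Adam learning rate.
#' @param epochsFixed,epochsDecay epochs at fixed lr / with linear decay.
#' @param iterationsPerEpoch minibatch iterations per epoch.
#' @param batchSize minibatch size (1, the inherited default).
#' @param earlyStopTolerance epochs without improvement before moving to the
#'   decay phase / stopping, length 2.
#' @param improvementTol minimum decrease of the epoch-mean total loss that
#'   counts as an improvement.
#' @param seed integer seed controlling initialization and sampling.
#' @param weights a [lossWeights()] object.
#' @param sampling `"random-patient-slice"` or `"same-patient-random-slice"`.
#' @param augmentation list with `translation` (px), `rotation` (deg),
#'   `scale`, `shear` (deg), `flip` (probability).
#' @param mode `"dicyc"` (full model), `"cyclegan"` (no deformation modules,
#'   no alignment) or `"cyclegan+align"` (alignment loss but no deformation
#'   modules).
#' @param alignMeasure `"nmi"`, `"gcc"` or `"plugin:<name>"`.
#' @param generator a [generatorSpec()].
#' @param transformer a [transformerSpec()].
#' @param discriminatorBase first-layer channels of the discriminators.
#' @param poolSize historical fake-image pool size.
#' @param ganForm `"lsgan"` or `"log"`.
#' @return A list with class `"trainConfig"`.
#' @export
trainConfig <- function(lr = 2e-4, epochsFixed = 100L, epochsDecay = 100L,
                        iterationsPerEpoch = 6000L, batchSize = 1L,
                        earlyStopTolerance = c(10L, 20L),
                        improvementTol = 1e-4, seed = 1L,
                        weights = lossWeights(),
                        sampling = c("random-patient-slice",
                                     "same-patient-random-slice"),
                        augmentation = list(translation = 4, rotation = 10,
                                            scale = 0.05, shear = 5,
                                            flip = 0.5),
                        mode = c("dicyc", "cyclegan", "cyclegan+align"),
                        alignMeasure = "nmi",
                        generator = generatorSpec(),
                        transformer = transformerSpec(),
                        discriminatorBase = 64L, poolSize = 50L,
                        ganForm = "lsgan") {
  sampling <- match.arg(sampling)
  mode <- match.arg(mode)
  stopifnot(lr > 0, epochsFixed >= 0, epochsDecay >= 0,
            iterationsPerEpoch >= 0, batchSize == 1L,
            length(earlyStopTolerance) == 2, all(earlyStopTolerance > 0))
  structure(list(lr = lr, epochsFixed = as.integer(epochsFixed),
                 epochsDecay = as.integer(epochsDecay),
                 iterationsPerEpoch = as.integer(iterationsPerEpoch),
                 batchSize = as.integer(batchSize),
                 earlyStopTolerance = as.integer(earlyStopTolerance),
                 improvementTol = improvementTol, seed = as.integer(seed),
                 weights = weights, sampling = sampling,
                 augmentation = augmentation, mode = mode,
                 alignMeasure = alignMeasure, generator = generator,
                 transformer = transformer,
                 discriminatorBase = as.integer(discriminatorBase),
                 poolSize = as.integer(poolSize), ganForm = ganForm),
            class = "trainConfig")
}

#' Learning rate schedule
#'
#' Constant `lr` for the first `epochsFixed` epochs, then linear decay to 0
#' over `epochsDecay` epochs (0-based epoch index).
#'
#' @param epoch 0-based epoch index.
#' @param config a [trainConfig()].
#' @return Learning rate for that epoch.
#' @export
learningRate <- function(epoch, config) {
  total <- config$epochsFixed + config$epochsDecay
  if (epoch < 0 || epoch >= total) stop("epoch out of schedule range")
  if (epoch < config$epochsFixed) config$lr
  else config$lr * (1 - (epoch - config$epochsFixed) / config$epochsDecay)
}

#' Random affine augmentation
#'
#' One random affine resampling (translation, rotation, scale, shear,
#' horizontal flip), a pure function of the seed. Applied to generator inputs
#' only during training.
#'
#' @param image an [ImageSlice-class].
#' @param seed integer seed.
#' @param ranges list as in [trainConfig()]'s `augmentation`.
#' @return The augmented [ImageSlice-class].
#' @export
augmentAffine <- function(image, seed, ranges) {
  p <- pixels(image)
  H <- nrow(p); W <- ncol(p)
  par <- with_local_seed(seed, list(
    tx = stats::runif(1, -ranges$translation, ranges$translation),
    ty = stats::runif(1, -ranges$translation, ranges$translation),
    rot = stats::runif(1, -ranges$rotation, ranges$rotation) * pi / 180,
    sc = stats::runif(1, 1 - ranges$scale, 1 + ranges$scale),
    sh = stats::runif(1, -ranges$shear, ranges$shear) * pi / 180,
    flip = stats::runif(1) < ranges$flip))
  fld <- affine_field(H, W, par)
  resampleSlice(image, fld, padding = "border")
}

# pull-back sampling field of an affine map in normalized coordinates
affine_field <- function(H, W, par) {
  R <- matrix(c(cos(par$rot), -sin(par$rot), sin(par$rot), cos(par$rot)), 2, 2)
  Sh <- matrix(c(1, 0, tan(par$sh), 1), 2, 2)
  M <- par$sc * R %*% Sh
  if (par$flip) M <- M %*% diag(c(-1, 1))
  tn <- c(2 * par$tx / max(W - 1, 1), 2 * par$ty / max(H - 1, 1))
  g <- identityGrid(H, W)
  pts <- cbind(as.vector(g[, , 1]), as.vector(g[, , 2]))
  mapped <- pts %*% t(M)
  mapped <- sweep(mapped, 2, tn, "+")
  off <- array(0, dim = c(H, W, 2))
  off[, , 1] <- matrix(mapped[, 1], H, W) - g[, , 1]
  off[, , 2] <- matrix(mapped[, 2], H, W) - g[, , 2]
  displacementField(off)
}

#' Sample an unpaired minibatch
#'
#' `"random-patient-slice"` draws the two domain halves independently across
#' patients and slices; `"same-patient-random-slice"` draws both halves from
#' one randomly selected patient.
#'
#' @param dataset list with `A`, `B` (lists of [ImageSlice-class]) and
#'   `patientA`, `patientB` (character).
#' @param strategy sampling strategy.
#' @param seed integer seed.
#' @param batchSize slices per domain half.
#' @return List with `A`, `B` (lists of slices) and index vectors
#'   `indexA`, `indexB`.
#' @export
sampleMinibatch <- function(dataset,
                            strategy = c("random-patient-slice",
                                         "same-patient-random-slice"),
                            seed = 1L, batchSize = 1L) {
  strategy <- match.arg(strategy)
  nA <- length(dataset$A); nB <- length(dataset$B)
  if (nA == 0 || nB == 0) stop("both domains must be non-empty")
  with_local_seed(seed, {
    if (strategy == "random-patient-slice") {
      ia <- sample.int(nA, batchSize, replace = TRUE)
      ib <- sample.int(nB, batchSize, replace = TRUE)
    } else {
      common <- intersect(unique(dataset$patientA), unique(dataset$patientB))
      if (length(common) == 0) stop("no shared patients between domains")
      pat <- common[sample.int(length(common), 1)]
      ia <- sample(which(dataset$patientA == pat), batchSize, replace = TRUE)
      ib <- sample(which(dataset$patientB == pat), batchSize, replace = TRUE)
    }
    list(A = dataset$A[ia], B = dataset$B[ib], indexA = ia, indexB = ib)
  })
}

# historical fake-image pool (inherited vanilla default, size 50)
pool_new <- function(size) {
  e <- new.env(parent = emptyenv())
  e$size <- size; e$imgs <- list()
  e
}

pool_query <- function(pool, img) {
  if (pool$size == 0) return(img)
  if (length(pool$imgs) < pool$size) {
    pool$imgs[[length(pool$imgs) + 1L]] <- img
    return(img)
  }
  if (stats::runif(1) < 0.5) {
    k <- sample.int(pool$size, 1)
    old <- pool$imgs[[k]]
    pool$imgs[[k]] <- img
    old
  } else img
}

#' Initialize a training state
#'
#' Builds both generator directions, both transformers, both discriminators
#' and their optimizers under the configuration seed.
#'
#' @param config a [trainConfig()].
#' @return A training-state environment (class `"dicyc_train_state"`).
#' @export
newTrainState <- function(config) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  with_local_seed(config$seed, {
    st$genAB <- buildGenerator(config$generator)
    st$genBA <- buildGenerator(config$generator)
    lc <- config$generator$downsampleChannels[2]
    st$transAB <- buildTransformer(config$transformer, latentChannels = lc)
    st$transBA <- buildTransformer(config$transformer, latentChannels = lc)
    st$dA <- buildDiscriminator(1L, config$discriminatorBase)
    st$dB <- buildDiscriminator(1L, config$discriminatorBase)
  })
  st$optG <- adam_new(c(st$genAB$params, st$genBA$params), lr = config$lr)
  st$optT <- adam_new(c(st$transAB$params, st$transBA$params), lr = config$lr)
  st$optD <- adam_new(c(st$dA$params, st$dB$params), lr = config$lr)
  st$poolA <- pool_new(config$poolSize)
  st$poolB <- pool_new(config$poolSize)
  st$epoch <- 0L
  st$iteration <- 0L
  st$history <- list()
  class(st) <- "dicyc_train_state"
  st
}

all_state_params <- function(st)
  c(st$genAB$params, st$genBA$params, st$transAB$params, st$transBA$params,
    st$dA$params, st$dB$params)

# deformed passes for both directions on tape nodes
deformed_passes <- function(st, xA, xB) {
  encA <- st$genAB$encode(xA, offsets = TRUE)
  encB <- st$genBA$encode(xB, offsets = TRUE)
  fdAB <- local({
    pts <- st$transAB$forward(encA$latent, encB$latent)
    shp <- dim(vof(encA$latent))[1:2]
    gf <- global_field_node(pts, st$transAB$sourceGrid, shp)
    warped <- ad_grid_sample(encA$latent,
                             ad_add(ad_tensor(identityGrid(shp[1], shp[2])), gf),
                             "border")
    list(out = st$genAB$decode(warped), pts = pts, gf = gf)
  })
  fdBA <- local({
    pts <- st$transBA$forward(encB$latent, encA$latent)
    shp <- dim(vof(encB$latent))[1:2]
    gf <- global_field_node(pts, st$transBA$sourceGrid, shp)
    warped <- ad_grid_sample(encB$latent,
                             ad_add(ad_tensor(identityGrid(shp[1], shp[2])), gf),
                             "border")
    list(out = st$genBA$decode(warped), pts = pts, gf = gf)
  })
  list(encA = encA, encB = encB, xTB = fdAB$out, xTA = fdBA$out,
       ptsAB = fdAB$pts, ptsBA = fdBA$pts)
}

# deformed round trips for the deformation-invariant cycle loss
dicyc_nodes <- function(st, dp, xA, xB) {
  encTB <- st$genBA$encode(dp$xTB, offsets = TRUE)
  ptsBA <- st$transBA$forward(encTB$latent, dp$encA$latent)
  shp <- dim(vof(encTB$latent))[1:2]
  gfBA <- global_field_node(ptsBA, st$transBA$sourceGrid, shp)
  recTA <- st$genBA$decode(ad_grid_sample(
    encTB$latent, ad_add(ad_tensor(identityGrid(shp[1], shp[2])), gfBA),
    "border"))
  encTA <- st$genAB$encode(dp$xTA, offsets = TRUE)
  ptsAB <- st$transAB$forward(encTA$latent, dp$encB$latent)
  gfAB <- global_field_node(ptsAB, st$transAB$sourceGrid, shp)
  recTB <- st$genAB$decode(ad_grid_sample(
    encTA$latent, ad_add(ad_tensor(identityGrid(shp[1], shp[2])), gfAB),
    "border"))
  ad_add(mae_node(recTA, xA), mae_node(recTB, xB))
}

#' One expectation step
#'
#' Updates only the global transformer parameters of both directions, driven
#' by the adversarial generator terms on the deformed outputs plus the
#' weighted deformation-invariant cycle term (the only loss terms that depend
#' on the global deformation). All other parameters are untouched, bitwise.
#'
#' @param state a training state from [newTrainState()].
#' @param batch list with numeric matrices `A` and `B` (generator inputs).
#' @return The state, invisibly.
#' @export
eStep <- function(state, batch) {
  if (state$config$mode != "dicyc") return(invisible(state))
  xA <- ad_tensor(array(batch$A, dim = c(dim(batch$A), 1L)))
  xB <- ad_tensor(array(batch$B, dim = c(dim(batch$B), 1L)))
  dp <- deformed_passes(state, xA, xB)
  ganAB <- lsgan_g_node(state$dB$forward(dp$xTB))
  ganBA <- lsgan_g_node(state$dA$forward(dp$xTA))
  dic <- dicyc_nodes(state, dp, xA, xB)
  loss <- ad_add(ad_add(ganAB, ganBA),
                 ad_mul(dic, state$config$weights@lambdaDicyc))
  ad_zero_grad(all_state_params(state))
  ad_backward(loss)
  adam_step(state$optT)
  state$lastControlPoints <- list(AB = vof(dp$ptsAB), BA = vof(dp$ptsBA))
  invisible(state)
}

#' One maximization step
#'
#' Runs the undeformed and deformed passes for both directions, assembles the
#' weighted total loss, updates the synthesis parameters (encoder, decoder
#' and local offset convolutions), then updates the discriminators against
#' the historical fake pool. Returns the loss breakdown.
#'
#' @param state training state.
#' @param batch list with matrices `A`, `B` (generator inputs) and optionally
#'   `realA`, `realB` (unaugmented images shown to the discriminators;
#'   default the same).
#' @return A list `(state, breakdown)` where breakdown is a
#'   [LossBreakdown-class].
#' @export
mStep <- function(state, batch) {
  cf <- state$config
  mode <- cf$mode
  W <- cf$weights
  realA <- if (is.null(batch$realA)) batch$A else batch$realA
  realB <- if (is.null(batch$realB)) batch$B else batch$realB
  xA <- ad_tensor(array(batch$A, dim = c(dim(batch$A), 1L)))
  xB <- ad_tensor(array(batch$B, dim = c(dim(batch$B), 1L)))

  # undeformed passes and cycles
  xhatB <- state$genAB$decode(state$genAB$encode(xA, offsets = FALSE)$latent)
  xhatA <- state$genBA$decode(state$genBA$encode(xB, offsets = FALSE)$latent)
  recA <- state$genBA$decode(state$genBA$encode(xhatB, offsets = FALSE)$latent)
  recB <- state$genAB$decode(state$genAB$encode(xhatA, offsets = FALSE)$latent)
  cyc <- ad_add(mae_node(recA, xA), mae_node(recB, xB))

  if (mode == "dicyc") {
    dp <- deformed_passes(state, xA, xB)
    fakeB <- dp$xTB; fakeA <- dp$xTA
    dic <- dicyc_nodes(state, dp, xA, xB)
  } else {
    fakeB <- xhatB; fakeA <- xhatA
    dic <- ad_tensor(0)
  }
  ganAB <- lsgan_g_node(state$dB$forward(fakeB))
  ganBA <- lsgan_g_node(state$dA$forward(fakeA))

  if (mode != "cyclegan") {
    m <- if (is.function(cf$alignMeasure)) cf$alignMeasure
         else alignmentMeasure(cf$alignMeasure, differentiable = TRUE)
    align <- ad_sub(2, ad_add(m(xA, xhatB), m(xB, xhatA)))
  } else align <- ad_tensor(0)

  loss <- ad_add(ad_add(ganAB, ganBA),
                 ad_add(ad_mul(align, W@lambdaAlign),
                        ad_add(ad_mul(cyc, W@lambdaCyc),
                               ad_mul(dic, W@lambdaDicyc))))
  if (!is.finite(vof(loss))) {
    parts <- c(ganAB = vof(ganAB), ganBA = vof(ganBA), align = vof(align),
               cyc = vof(cyc), dicyc = vof(dic))
    stop("non-finite loss term: ",
         paste(names(parts)[!is.finite(parts)], collapse = ", "))
  }
  ad_zero_grad(all_state_params(state))
  ad_backward(loss)
  adam_step(state$optG)

  # discriminator step on real vs pooled deformed fakes
  fb <- pool_query(state$poolB, vof(fakeB))
  fa <- pool_query(state$poolA, vof(fakeA))
  dlossB <- lsgan_d_node(
    state$dB$forward(ad_tensor(array(realB, dim = c(dim(realB), 1L)))),
    state$dB$forward(ad_tensor(fb)))
  dlossA <- lsgan_d_node(
    state$dA$forward(ad_tensor(array(realA, dim = c(dim(realA), 1L)))),
    state$dA$forward(ad_tensor(fa)))
  dloss <- ad_add(dlossA, dlossB)
  ad_zero_grad(all_state_params(state))
  ad_backward(dloss)
  adam_step(state$optD)

  breakdown <- totalLoss(vof(ganAB), vof(ganBA), vof(align), vof(cyc),
                         vof(dic), W)
  list(state = state, breakdown = breakdown)
}

#' Train a model
#'
#' Alternates [eStep()] and [mStep()] every iteration, applies the linear
#' learning-rate schedule with the two-phase early-stopping rule (no
#' improvement of the epoch-mean total loss for 10 epochs moves training to
#' the decay phase; 20 further non-improving epochs stop it), logs a
#' per-iteration loss breakdown, and optionally writes per-epoch checkpoints
#' and a CSV loss log.
#'
#' @param config a [trainConfig()].
#' @param dataset training set as produced by [phantomTrainingSet()].
#' @param outDir optional output directory for checkpoints and the loss CSV.
#' @param verbose print one line per epoch.
#' @return The final training state (class `"dicyc_train_state"`).
#' @export
trainDicyc <- function(config, dataset, outDir = NULL, verbose = FALSE) {
  state <- newTrainState(config)
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  total_epochs <- config$epochsFixed + config$epochsDecay
  if (total_epochs == 0L || config$iterationsPerEpoch == 0L) return(state)
  set.seed(config$seed + 1L)
  best <- Inf; no_improve <- 0L; sched <- 0L
  while (sched < total_epochs) {
    lr <- learningRate(sched, config)
    state$optG$lr <- lr; state$optT$lr <- lr; state$optD$lr <- lr
    etot <- numeric(config$iterationsPerEpoch)
    for (it in seq_len(config$iterationsPerEpoch)) {
      bseed <- sample.int(2147483646L, 1)
      mb <- sampleMinibatch(dataset, config$sampling, seed = bseed)
      aseed <- sample.int(2147483646L, 2)
      gA <- augmentAffine(mb$A[[1]], aseed[1], config$augmentation)
      gB <- augmentAffine(mb$B[[1]], aseed[2], config$augmentation)
      batch <- list(A = pixels(gA), B = pixels(gB),
                    realA = pixels(mb$A[[1]]), realB = pixels(mb$B[[1]]))
      eStep(state, batch)
      res <- mStep(state, batch)
      bd <- res$breakdown
      state$iteration <- state$iteration + 1L
      etot[it] <- bd@total
      state$history[[length(state$history) + 1L]] <- data.frame(
        iteration = state$iteration, epoch = sched, ganAB = bd@ganAB,
        ganBA = bd@ganBA, align = bd@align, cyc = bd@cyc, dicyc = bd@dicyc,
        total = bd@total, lr = lr)
    }
    em <- mean(etot)
    state$epoch <- state$epoch + 1L
    if (verbose)
      message(sprintf("epoch %d (schedule %d): mean total %.4f", state$epoch,
                      sched, em))
    if (!is.null(outDir)) {
      saveCheckpoint(state, file.path(outDir, sprintf("epoch_%03d.bin", state$epoch)))
      utils::write.csv(lossHistory(state),
                       file.path(outDir, "loss_log.csv"), row.names = FALSE)
    }
    if (em < best - config$improvementTol) { best <- em; no_improve <- 0L }
    else no_improve <- no_improve + 1L
    if (sched < config$epochsFixed && no_improve >= config$earlyStopTolerance[1]) {
      sched <- config$epochsFixed
      no_improve <- 0L
      if (sched >= total_epochs) break
    } else if (sched >= config$epochsFixed &&
               no_improve >= config$earlyStopTolerance[2]) {
      break
    } else {
      sched <- sched + 1L
    }
  }
  state
}

#' Per-iteration loss history as a data frame
#' @param state a training state.
#' @return data.frame with iteration, epoch, the five loss terms, total, lr.
#' @export
lossHistory <- function(state) {
  if (length(state$history) == 0) return(data.frame())
  do.call(rbind, state$history)
}

# Pre-fit both generators toward the identity mapping (L1 reconstruction) and
# the discriminators toward separating the real images from the current
# undeformed fakes. Used by the deformation-recovery harness: on a
# same-modality toy pair this leaves geometry as the only adversarial signal,
# so subsequent E-steps have to explain the domain deformation through the
# transformer.
pretrain_identity <- function(state, xA, xB, steps = 200L, d_steps = 100L,
                              lr = 1e-3) {
  optG <- adam_new(c(state$genAB$params, state$genBA$params), lr = lr)
  an <- ad_tensor(array(xA, dim = c(dim(xA), 1L)))
  bn <- ad_tensor(array(xB, dim = c(dim(xB), 1L)))
  for (i in seq_len(steps)) {
    outB <- state$genAB$decode(state$genAB$encode(an, offsets = FALSE)$latent)
    outA <- state$genBA$decode(state$genBA$encode(bn, offsets = FALSE)$latent)
    loss <- ad_add(mae_node(outB, an), mae_node(outA, bn))
    ad_zero_grad(all_state_params(state))
    ad_backward(loss)
    adam_step(optG)
  }
  for (i in seq_len(d_steps)) {
    fakeB <- state$genAB$decode(state$genAB$encode(an, offsets = FALSE)$latent)
    fakeA <- state$genBA$decode(state$genBA$encode(bn, offsets = FALSE)$latent)
    dl <- ad_add(lsgan_d_node(state$dB$forward(bn),
                              state$dB$forward(ad_detach(fakeB))),
                 lsgan_d_node(state$dA$forward(an),
                              state$dA$forward(ad_detach(fakeA))))
    ad_zero_grad(all_state_params(state))
    ad_backward(dl)
    adam_step(state$optD)
  }
  invisible(state)
}

#' Save a training checkpoint
#'
#' Stores all network parameter values, optimizer state, the RNG state and
#' the loss history, so that training resumes bit-compatibly.
#'
#' @param state training state.
#' @param path output file.
#' @export
saveCheckpoint <- function(state, path) {
  rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  obj <- list(config = state$config,
              params = params_values(all_state_params(state)),
              adam = lapply(list(state$optG, state$optT, state$optD),
                            function(o) list(m = o$m, v = o$v, t = o$t, lr = o$lr)),
              pools = list(A = state$poolA$imgs, B = state$poolB$imgs),
              epoch = state$epoch, iteration = state$iteration,
              history = state$history, rng = rng)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path checkpoint written by [saveCheckpoint()].
#' @return A restored training state.
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  state <- newTrainState(obj$config)
  params_restore(all_state_params(state), obj$params)
  opts <- list(state$optG, state$optT, state$optD)
  for (i in 1:3) {
    opts[[i]]$m <- obj$adam[[i]]$m
    opts[[i]]$v <- obj$adam[[i]]$v
    opts[[i]]$t <- obj$adam[[i]]$t
    opts[[i]]$lr <- obj$adam[[i]]$lr
  }
  state$poolA$imgs <- obj$pools$A
  state$poolB$imgs <- obj$pools$B
  state$epoch <- obj$epoch
  state$iteration <- obj$iteration
  state$history <- obj$history
  if (!is.null(obj$rng)) assign(".Random.seed", obj$rng, envir = globalenv())
  state
}
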