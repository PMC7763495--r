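# The deformation-invariant generator (encoder F with modified deformable
# insertions, decoder G, TPS transformer T) and the 70x70 patch
# discriminator. Each generator direction produces two outputs per forward
# run: an undeformed image computed with all deformation parameters bypassed,
# and a deformed image computed with the learned local offset fields and the
# TPS global warp applied to the latent features.

#' Generator architecture specification
#'
#' The defaults reproduce the reference architecture: a 7x7 input convolution
#' with 64 channels, two stride-2 downsampling 3x3 convolutions with 128 and
#' 256 channels, six residual blocks at 256 channels, a mirrored decoder, and
#' four deformable insertion points (before the input convolution, before
#' each downsampling convolution and before the residual stack). All
#' normalization is instance normalization without learned affine parameters.
#'
#' @param baseChannels channels of the first convolution (default 64).
#' @param downsampleChannels channels of the two downsampling stages.
#' @param resnetBlocks number of residual blocks (default 6).
#' @param firstKernel kernel size of the first and last convolution.
#' @param otherKernels kernel size everywhere else.
#' @param inChannels input channels (grayscale slices: 1).
#' @return A list with class `"generatorSpec"`.
#' @export
generatorSpec <- function(baseChannels = 64L, downsampleChannels = c(128L, 256L),
                          resnetBlocks = 6L, firstKernel = 7L, otherKernels = 3L,
                          inChannels = 1L) {
  stopifnot(baseChannels >= 1, length(downsampleChannels) == 2,
            resnetBlocks >= 1, firstKernel %% 2 == 1, otherKernels %% 2 == 1)
  structure(list(baseChannels = as.integer(baseChannels),
                 downsampleChannels = as.integer(downsampleChannels),
                 resnetBlocks = as.integer(resnetBlocks),
                 firstKernel = as.integer(firstKernel),
                 otherKernels = as.integer(otherKernels),
                 inChannels = as.integer(inChannels)),
            class = "generatorSpec")
}

#' Transformer (global deformation) specification
#'
#' The transformer regresses the target coordinates of a regular `gridSide^2`
#' control grid from the concatenated latent features of the two directions.
#' Each latent branch is reduced by two stride-2 3x3 convolutions; after
#' concatenation and global average pooling one hidden fully-connected layer
#' feeds a zero-initialized output layer. Predicted points are
#' `clamp(grid + maxShift * tanh(raw), -1, 1)`, so a zero-initialized head
#' yields exactly the regular grid (identity deformation) and outputs are
#' always inside the normalized square.
#'
#' @param gridSide control grid side (default 6, i.e. 36 points).
#' @param reducerChannels channels of the two reducing convolutions.
#' @param hidden width of the hidden fully-connected layer.
#' @param maxShift maximum control point displacement in normalized units
#'   (default 0.4, one control-cell spacing of the 6x6 grid).
#' @return A list with class `"transformerSpec"`.
#' @export
transformerSpec <- function(gridSide = 6L, reducerChannels = c(64L, 32L),
                            hidden = 128L, maxShift = 0.4) {
  stopifnot(gridSide >= 2, length(reducerChannels) == 2, maxShift > 0)
  structure(list(gridSide = as.integer(gridSide),
                 reducerChannels = as.integer(reducerChannels),
                 hidden = as.integer(hidden), maxShift = maxShift),
            class = "transformerSpec")
}

# warp a feature node by a displacement-field node (normalized coordinates)
warp_by_field <- function(x, field, padding = "border") {
  d <- dim(vof(x))
  grid <- ad_add(ad_tensor(identityGrid(d[1], d[2])), field)
  ad_grid_sample(x, grid, padding)
}

#' Build a generator (encoder, decoder, deformable insertions)
#'
#' @param spec a [generatorSpec()].
#' @return A generator handle (environment) with `encode`/`decode` closures,
#'   parameter lists (`params`, `synth_params`, `offset_params`) and an
#'   architecture table used for parameter/MAC accounting. Offset
#'   convolutions are 3x3, zero-initialized (identity deformation at the
#'   start of training), and produce a single 2-channel displacement field
#'   shared by all feature channels.
#' @export
buildGenerator <- function(spec = generatorSpec()) {
  stopifnot(inherits(spec, "generatorSpec"))
  b <- spec$baseChannels
  d1 <- spec$downsampleChannels[1]
  d2 <- spec$downsampleChannels[2]
  k1 <- spec$firstKernel; k <- spec$otherKernels
  p1 <- (k1 - 1L) %/% 2L; p <- (k - 1L) %/% 2L

  off <- list(
    nn_conv(k, k, spec$inChannels, 2L, pad = p, init = "zero"),
    nn_conv(k, k, b, 2L, pad = p, init = "zero"),
    nn_conv(k, k, d1, 2L, pad = p, init = "zero"),
    nn_conv(k, k, d2, 2L, pad = p, init = "zero"))
  e1 <- nn_conv(k1, k1, spec$inChannels, b, pad = p1, pad_mode = "reflect")
  e2 <- nn_conv(k, k, b, d1, stride = 2L, pad = p)
  e3 <- nn_conv(k, k, d1, d2, stride = 2L, pad = p)
  res <- lapply(seq_len(spec$resnetBlocks), function(i) nn_resnet_block(d2, k))
  names(res) <- paste0("res", seq_along(res))
  u1 <- nn_conv(k, k, d2, d1, pad = p, pad_mode = "reflect")
  u2 <- nn_conv(k, k, d1, b, pad = p, pad_mode = "reflect")
  out <- nn_conv(k1, k1, b, spec$inChannels, pad = p1, pad_mode = "reflect")

  g <- new.env(parent = emptyenv())
  g$spec <- spec
  g$off <- off
  g$layers <- c(list(e1 = e1, e2 = e2, e3 = e3), res,
                list(u1 = u1, u2 = u2, out = out))
  g$synth_params <- layer_params(list(e1, e2, e3)) |>
    c(layer_params(res), layer_params(list(u1, u2, out)))
  g$offset_params <- layer_params(off)
  g$params <- c(g$synth_params, g$offset_params)
  g$arch <- c(list(e1$desc, e2$desc, e3$desc),
              unlist(lapply(res, function(r) r$desc$convs), recursive = FALSE),
              list(list(kind = "upsample2"), u1$desc,
                   list(kind = "upsample2"), u2$desc, out$desc))
  g$arch_offsets <- lapply(off, function(l) l$desc)

  g$encode <- function(x, offsets = FALSE) {
    x <- ad_wrap(x)
    fields <- list()
    if (offsets) { f <- off[[1]]$forward(x); fields$input <- f; x <- warp_by_field(x, f) }
    x <- ad_relu(ad_instance_norm(e1$forward(x)))
    if (offsets) { f <- off[[2]]$forward(x); fields$down1 <- f; x <- warp_by_field(x, f) }
    x <- ad_relu(ad_instance_norm(e2$forward(x)))
    if (offsets) { f <- off[[3]]$forward(x); fields$down2 <- f; x <- warp_by_field(x, f) }
    x <- ad_relu(ad_instance_norm(e3$forward(x)))
    if (offsets) { f <- off[[4]]$forward(x); fields$resnet <- f; x <- warp_by_field(x, f) }
    for (r in res) x <- r$forward(x)
    list(latent = x, fields = fields)
  }
  g$decode <- function(z) {
    z <- ad_relu(ad_instance_norm(u1$forward(ad_upsample2(z))))
    z <- ad_relu(ad_instance_norm(u2$forward(ad_upsample2(z))))
    ad_tanh(out$forward(z))
  }
  class(g) <- "dicyc_generator"
  g
}

#' Build the global TPS transformer head
#'
#' @param spec a [transformerSpec()].
#' @param latentChannels channel count of the encoder latents it consumes.
#' @return A transformer handle with a `forward(latentA, latentB)` closure
#'   returning the predicted control point node, plus parameter lists.
#' @export
buildTransformer <- function(spec = transformerSpec(), latentChannels = 256L) {
  stopifnot(inherits(spec, "transformerSpec"))
  r1 <- spec$reducerChannels[1]; r2 <- spec$reducerChannels[2]
  n2 <- spec$gridSide^2
  brA <- list(nn_conv(3L, 3L, latentChannels, r1, stride = 2L, pad = 1L),
              nn_conv(3L, 3L, r1, r2, stride = 2L, pad = 1L))
  brB <- list(nn_conv(3L, 3L, latentChannels, r1, stride = 2L, pad = 1L),
              nn_conv(3L, 3L, r1, r2, stride = 2L, pad = 1L))
  fc1 <- nn_linear(2L * r2, spec$hidden)
  fc2 <- nn_linear(spec$hidden, 2L * n2, init = "zero")
  grid_pts <- controlPoints(regularControlGrid(spec$gridSide))

  t <- new.env(parent = emptyenv())
  t$spec <- spec
  t$sourceGrid <- regularControlGrid(spec$gridSide)
  t$params <- c(layer_params(brA), layer_params(brB), fc1$params, fc2$params)
  t$arch <- c(lapply(brA, function(l) l$desc), lapply(brB, function(l) l$desc),
              list(fc1$desc, fc2$desc))
  t$forward <- function(latentA, latentB) {
    za <- ad_wrap(latentA); zb <- ad_wrap(latentB)
    for (l in brA) za <- ad_relu(l$forward(za))
    for (l in brB) zb <- ad_relu(l$forward(zb))
    v <- ad_gap(ad_concat_c(za, zb))
    raw <- fc2$forward(ad_relu(fc1$forward(v)))
    delta <- ad_mul(ad_tanh(ad_reshape(raw, c(n2, 2L))), spec$maxShift)
    ad_clamp(ad_add(delta, ad_tensor(grid_pts)), -1, 1)
  }
  class(t) <- "dicyc_transformer"
  t
}

#' Build the 70x70 patch discriminator
#'
#' Four 4x4 convolutions with channels 64/128/256/512 (strides 2,2,2,1) and a
#' final 4x4 convolution to a 1-channel patch map; instance normalization
#' without learned affine on the middle layers; leaky ReLU (0.2) activations.
#' With one input channel the handle holds 2,762,689 trainable parameters and
#' each output unit has a 70x70 receptive field.
#'
#' @param inChannels number of input channels (default 1).
#' @param baseChannels channels of the first layer (default 64).
#' @param norm `"instance"` (default) or `"none"`. Instance normalization
#'   mixes per-channel global statistics into the gradients; the `"none"`
#'   variant exposes the purely convolutional 70x70 receptive field to
#'   gradient probing.
#' @return A discriminator handle with `forward`, `params`, `arch`.
#' @export
buildDiscriminator <- function(inChannels = 1L, baseChannels = 64L,
                               norm = c("instance", "none")) {
  norm <- match.arg(norm)
  stopifnot(inChannels >= 1)
  b <- as.integer(baseChannels)
  l1 <- nn_conv(4L, 4L, inChannels, b, stride = 2L, pad = 1L)
  l2 <- nn_conv(4L, 4L, b, 2L * b, stride = 2L, pad = 1L)
  l3 <- nn_conv(4L, 4L, 2L * b, 4L * b, stride = 2L, pad = 1L)
  l4 <- nn_conv(4L, 4L, 4L * b, 8L * b, stride = 1L, pad = 1L)
  l5 <- nn_conv(4L, 4L, 8L * b, 1L, stride = 1L, pad = 1L)
  dsc <- new.env(parent = emptyenv())
  dsc$params <- layer_params(list(l1, l2, l3, l4, l5))
  dsc$arch <- list(l1$desc, l2$desc, l3$desc, l4$desc, l5$desc)
  nrm <- if (norm == "instance") ad_instance_norm else identity
  dsc$forward <- function(x) {
    x <- ad_lrelu(l1$forward(ad_wrap(x)))
    x <- ad_lrelu(nrm(l2$forward(x)))
    x <- ad_lrelu(nrm(l3$forward(x)))
    x <- ad_lrelu(nrm(l4$forward(x)))
    l5$forward(x)
  }
  class(dsc) <- "dicyc_discriminator"
  dsc
}

# image <-> node helpers
slice_to_node <- function(x) {
  p <- if (is(x, "ImageSlice")) pixels(x) else as.matrix(x)
  ad_tensor(array(p, dim = c(dim(p), 1L)))
}

node_to_matrix <- function(node) {
  v <- vof(node)
  matrix(v, dim(v)[1], dim(v)[2])
}

# dense global-field node from predicted control points (differentiable)
global_field_node <- function(points, sourceGrid, shape) {
  M <- tps_linear_operator(sourceGrid, shape)
  idp <- cbind(as.vector(identityGrid(shape[1], shape[2])[, , 1]),
               as.vector(identityGrid(shape[1], shape[2])[, , 2]))
  flat <- ad_sub(ad_matmul(ad_tensor(M), points), ad_tensor(idp))
  ad_reshape(flat, c(shape[1], shape[2], 2L))
}

# Deformed forward pass on tape nodes: encode with offsets, warp the latent
# by the TPS global field predicted from (own latent, opposite latent),
# decode. Returns all intermediate nodes for loss construction.
forward_deformed_nodes <- function(gen, trans, xnode, oppositeLatent) {
  enc <- gen$encode(xnode, offsets = TRUE)
  pts <- trans$forward(enc$latent, oppositeLatent)
  shp <- dim(vof(enc$latent))[1:2]
  gf <- global_field_node(pts, trans$sourceGrid, shp)
  warped <- ad_grid_sample(enc$latent,
                           ad_add(ad_tensor(identityGrid(shp[1], shp[2])), gf),
                           "border")
  list(deformed = gen$decode(warped), latent = enc$latent,
       fields = enc$fields, points = pts, global_field = gf)
}

#' Undeformed forward pass of a generator
#'
#' Runs the pure synthesis path: all offset fields are bypassed and no global
#' warp is applied. This is the prediction-time path.
#'
#' @param generator a handle from [buildGenerator()].
#' @param x an [ImageSlice-class] or numeric matrix with sides divisible by 4.
#' @return An [ImageSlice-class] with the synthesized image.
#' @export
forwardUndeformed <- function(generator, x) {
  node <- slice_to_node(x)
  d <- dim(vof(node))
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0)
    stop("input sides must be divisible by 4")
  out <- generator$decode(generator$encode(node, offsets = FALSE)$latent)
  dom <- if (is(x, "ImageSlice")) x@domain else "A"
  id <- if (is(x, "ImageSlice")) paste0(x@id, "_synth") else "synth"
  imageSlice(node_to_matrix(out), domain = dom, id = id)
}

#' Extract the encoder latent of an image
#'
#' @param generator a generator handle.
#' @param x an [ImageSlice-class] or matrix.
#' @param offsets apply the deformable (offset) path (default TRUE, the
#'   deformed-pass latent).
#' @return Numeric array H/4 x W/4 x C of latent features.
#' @export
encodeLatent <- function(generator, x, offsets = TRUE) {
  vof(generator$encode(slice_to_node(x), offsets = offsets)$latent)
}

#' Deformed (two-output) forward pass of a generator direction
#'
#' Runs the encoder with the modified deformable convolutions active, warps
#' the latent features by the TPS global field predicted by the transformer
#' from the concatenation of the two directions' latents, and decodes. Both
#' the undeformed and the deformed synthesis are returned, together with the
#' deformation fields used. The opposite-direction latent is a training-time
#' input; prediction uses [forwardUndeformed()] only.
#'
#' @param generator generator handle for this direction.
#' @param transformer transformer handle for this direction.
#' @param x source [ImageSlice-class] or matrix.
#' @param oppositeLatent latent array of the opposite encoder on the other
#'   domain's minibatch image (see [encodeLatent()]).
#' @return A [DualSynthesis-class] object.
#' @export
forwardDeformed <- function(generator, transformer, x, oppositeLatent) {
  if (missing(oppositeLatent) || is.null(oppositeLatent))
    stop("forwardDeformed: the opposite-direction latent is required")
  node <- slice_to_node(x)
  fd <- forward_deformed_nodes(generator, transformer, node, ad_tensor(oppositeLatent))
  und <- generator$decode(generator$encode(node, offsets = FALSE)$latent)
  dom <- if (is(x, "ImageSlice")) x@domain else "A"
  id <- if (is(x, "ImageSlice")) x@id else ""
  new("DualSynthesis",
      undeformed = imageSlice(node_to_matrix(und), domain = dom,
                              id = paste0(id, "_synth")),
      deformed = imageSlice(node_to_matrix(fd$deformed), domain = dom,
                            id = paste0(id, "_synthT")),
      localFields = lapply(fd$fields, function(f) displacementField(vof(f))),
      globalField = displacementField(vof(fd$global_field)),
      controlPts = controlPointSet(pmin(pmax(vof(fd$points), -1), 1)))
}

#' Replay a recorded deformed pass
#'
#' Re-runs the synthesis path while substituting the recorded local offset
#' fields and global field for the learned predictions; reproduces the
#' deformed output of [forwardDeformed()].
#'
#' @param generator generator handle.
#' @param x the same input image.
#' @param localFields named list of [DisplacementField-class] objects (as
#'   recorded in a [DualSynthesis-class]).
#' @param globalField recorded global [DisplacementField-class].
#' @return An [ImageSlice-class].
#' @export
replayDeformed <- function(generator, x, localFields, globalField) {
  node <- slice_to_node(x)
  lr <- function(v) ad_relu(ad_instance_norm(v))
  fget <- function(name) ad_tensor(fieldOffsets(localFields[[name]]))
  h <- warp_by_field(node, fget("input"))
  h <- lr(generator$layers$e1$forward(h))
  h <- warp_by_field(h, fget("down1"))
  h <- lr(generator$layers$e2$forward(h))
  h <- warp_by_field(h, fget("down2"))
  h <- lr(generator$layers$e3$forward(h))
  h <- warp_by_field(h, fget("resnet"))
  for (nm in names(generator$layers))
    if (startsWith(nm, "res")) h <- generator$layers[[nm]]$forward(h)
  h <- warp_by_field(h, ad_tensor(fieldOffsets(globalField)))
  out <- generator$decode(h)
  imageSlice(node_to_matrix(out), id = "replay")
}
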