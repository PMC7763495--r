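# The modified deformable convolution: an "offset convolution" producing ONE
# 2-channel displacement field shared by all input feature channels,
# followed by a standard convolution on the resampled features. Compared with
# the original per-channel operator (2N offset maps for N channels), the
# shared field needs 1/N of the offset parameters and is equivalent to
# deforming the input once and passing it through a plain convolution.

#' Offset convolution specification
#'
#' @param inChannels input feature channels.
#' @param kernelSize kernel side (default 3).
#' @param init `"zero"` (default; identity deformation at construction) or
#'   `"random"`.
#' @return A list with class `"offsetConvSpec"`; output channel count is
#'   always 2 (one x map, one y map).
#' @export
offsetConvSpec <- function(inChannels, kernelSize = 3L,
                           init = c("zero", "random")) {
  init <- match.arg(init)
  stopifnot(inChannels >= 1, kernelSize %% 2 == 1)
  structure(list(inChannels = as.integer(inChannels),
                 kernelSize = as.integer(kernelSize), init = init,
                 outChannels = 2L),
            class = "offsetConvSpec")
}

#' Build a standard convolution layer
#'
#' @param kernel kernel side.
#' @param inChannels,outChannels channel counts.
#' @param stride stride.
#' @param pad padding (default "same" for odd kernels).
#' @param padMode `"zero"` or `"reflect"`.
#' @param init `"gaussian"` (sd 0.02) or `"zero"`.
#' @return A layer handle with `forward`, `params` and weight access via
#'   `$params$w`, `$params$b`.
#' @export
convLayer <- function(kernel, inChannels, outChannels, stride = 1L,
                      pad = (kernel - 1L) %/% 2L, padMode = "zero",
                      init = "gaussian") {
  nn_conv(kernel, kernel, inChannels, outChannels, stride = stride,
          pad = pad, pad_mode = padMode, init = init)
}

#' Build the offset convolution layer of a modified deformable block
#'
#' @param spec an [offsetConvSpec()].
#' @return A layer handle whose forward pass outputs 2 channels.
#' @export
buildOffsetConv <- function(spec) {
  stopifnot(inherits(spec, "offsetConvSpec"))
  nn_conv(spec$kernelSize, spec$kernelSize, spec$inChannels, 2L,
          pad = (spec$kernelSize - 1L) %/% 2L,
          init = if (spec$init == "zero") "zero" else "gaussian")
}

as_feature_array <- function(features) {
  if (is(features, "ImageSlice")) features <- pixels(features)
  if (is.matrix(features)) features <- array(features, dim = c(dim(features), 1L))
  features
}

#' Run an offset convolution
#'
#' A standard convolution with exactly 2 output channels, interpreted as the
#' (x, y) displacement field, in normalized coordinates, shared by all input
#' feature channels.
#'
#' @param features H x W x C array (or matrix / [ImageSlice-class]).
#' @param layer an offset layer from [buildOffsetConv()].
#' @return A [DisplacementField-class] of the same spatial shape.
#' @export
offsetConvolution <- function(features, layer) {
  f <- as_feature_array(features)
  if (dim(f)[3] != dim(layer$params$w$value)[3])
    stop("offsetConvolution: channel mismatch")
  displacementField(vof(layer$forward(ad_tensor(f))))
}

#' Apply a convolution layer to plain features
#'
#' @param layer a layer from [convLayer()].
#' @param features H x W x C array (or matrix).
#' @return Numeric output array.
#' @export
applyConv <- function(layer, features) {
  vof(layer$forward(ad_tensor(as_feature_array(features))))
}

#' Deformable application: resample features by a shared field, then convolve
#'
#' All channels are interpolated with the same 2-D field (border padding);
#' the standard convolution is then applied to the interpolated features.
#' During training the gradient flows through both the sampling locations and
#' the kernel weights. A zero field reduces bit-exactly to the plain
#' convolution.
#'
#' @param features H x W x C array (or matrix).
#' @param field a [DisplacementField-class] matching the spatial shape.
#' @param conv a layer from [convLayer()].
#' @return Numeric output array.
#' @export
deformableApply <- function(features, field, conv) {
  f <- as_feature_array(features)
  off <- fieldOffsets(field)
  if (!all(dim(off)[1:2] == dim(f)[1:2]))
    stop("deformableApply: field shape mismatch")
  warped <- resampleGrid(f, field, padding = "border")
  vof(conv$forward(ad_tensor(warped)))
}
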