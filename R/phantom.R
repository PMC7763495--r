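# Synthetic two-contrast phantom data with known, stored domain-specific
# deformations. Pairs of co-registered "modalities" render the same random
# anatomy (ellipses and annuli on a dark background) under two distinct
# monotone intensity mappings plus independent additive noise; the domain-B
# image is additionally warped by a random TPS (global) composed with a
# smooth random local field, and the exact field is stored so that alignment
# and recovery are checkable against ground truth.

with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Phantom generation configuration
#'
#' @param nShapes integer range (min, max) of shapes per phantom.
#' @param noiseSd standard deviation of the additive noise, on the unit
#'   intensity scale before normalization.
#' @param globalMagnitude standard deviation of the control-grid jitter that
#'   generates the global TPS deformation (normalized `[-1,1]` units).
#' @param localMagnitude standard deviation of the smooth local displacement
#'   field (normalized units).
#' @param localSigma Gaussian smoothing bandwidth of the local field, pixels.
#' @return A list with class `"phantomConfig"`.
#' @export
phantomConfig <- function(nShapes = c(3L, 8L), noiseSd = 0.03,
                          globalMagnitude = 0.05, localMagnitude = 0.01,
                          localSigma = 8) {
  if (length(nShapes) != 2 || any(nShapes < 1) || nShapes[1] > nShapes[2])
    stop("phantomConfig: nShapes must be an increasing pair of counts >= 1")
  if (noiseSd < 0 || globalMagnitude < 0 || localMagnitude < 0 || localSigma <= 0)
    stop("phantomConfig: invalid (negative) configuration value")
  structure(list(nShapes = as.integer(nShapes), noiseSd = noiseSd,
                 globalMagnitude = globalMagnitude,
                 localMagnitude = localMagnitude, localSigma = localSigma),
            class = "phantomConfig")
}

# monotone intensity mappings distinguishing the two "contrasts"
intensity_map_A <- function(s) s^0.6
intensity_map_B <- function(s) tanh(2.5 * s) / tanh(2.5)

# piecewise-constant anatomy of random ellipses and annuli on [-1,1]^2
draw_anatomy <- function(H, W, nShapes) {
  g <- identityGrid(H, W)
  gx <- g[, , 1]; gy <- g[, , 2]
  S <- matrix(0, H, W)
  k <- if (nShapes[1] == nShapes[2]) nShapes[1]
       else sample(nShapes[1]:nShapes[2], 1)
  for (i in seq_len(k)) {
    cx <- stats::runif(1, -0.55, 0.55); cy <- stats::runif(1, -0.55, 0.55)
    ax <- stats::runif(1, 0.12, 0.45); ay <- stats::runif(1, 0.12, 0.45)
    th <- stats::runif(1, 0, pi)
    val <- stats::runif(1, 0.25, 1)
    xr <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
    yr <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
    r2 <- (xr / ax)^2 + (yr / ay)^2
    mask <- r2 <= 1
    if (stats::runif(1) < 0.4) {                 # annulus: hollow center
      inner <- stats::runif(1, 0.3, 0.7)
      mask <- mask & r2 >= inner^2
    }
    S[mask] <- val
  }
  S
}

gaussian_smooth <- function(m, sigma) {
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  half <- (k - 1L) %/% 2L
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  ker <- outer(g1, g1); ker <- ker / sum(ker)
  w <- array(ker, dim = c(k, k, 1L, 1L))
  y <- cpp_conv2d_fw(array(m, dim = c(dim(m), 1L)), w, 0, 1L, half, 1L)
  matrix(y, nrow(m), ncol(m))
}

#' Apply a random domain-specific deformation to an image
#'
#' The deformation is a global thin-plate-spline displacement obtained by
#' jittering a regular 6x6 control grid (jitter standard deviation
#' `globalMagnitude`) composed with a Gaussian-smoothed white-noise local
#' field rescaled to standard deviation `localMagnitude`. Both magnitudes are
#' in normalized `[-1, 1]` coordinates. The exact composed field is returned
#' alongside the warped image; zero magnitudes return the input unchanged and
#' the zero field.
#'
#' @param image an [ImageSlice-class].
#' @param seed integer seed (generation is a pure function of it).
#' @param globalMagnitude,localMagnitude nonnegative deformation magnitudes.
#' @param localSigma Gaussian bandwidth of the local field, pixels.
#' @return A list with elements `image` (warped [ImageSlice-class]), `field`
#'   (the exact [DisplacementField-class] used), `coefficients`
#'   (the [TPSCoefficients-class] of the global part) and `localField`.
#' @export
simulateDomainDeformation <- function(image, seed, globalMagnitude = 0.05,
                                      localMagnitude = 0.01, localSigma = 8) {
  stopifnot(is(image, "ImageSlice"))
  if (globalMagnitude < 0 || localMagnitude < 0)
    stop("deformation magnitudes must be nonnegative")
  H <- nrow(pixels(image)); W <- ncol(pixels(image))
  with_local_seed(seed, {
    grid <- regularControlGrid(6)
    if (globalMagnitude > 0) {
      jit <- controlPoints(grid) +
        matrix(stats::rnorm(72, sd = globalMagnitude), 36, 2)
      target <- controlPointSet(pmin(pmax(jit, -1), 1))
      coeffs <- fitTPS(grid, target)
    } else coeffs <- identityTPS(grid)
    fg <- tpsDisplacement(coeffs, c(H, W))
    if (localMagnitude > 0) {
      raw <- array(stats::rnorm(H * W * 2), dim = c(H, W, 2))
      sm <- array(0, dim = c(H, W, 2))
      sm[, , 1] <- gaussian_smooth(raw[, , 1], localSigma)
      sm[, , 2] <- gaussian_smooth(raw[, , 2], localSigma)
      sm <- sm / stats::sd(sm) * localMagnitude
      fl <- displacementField(sm)
    } else fl <- zeroField(H, W)
    field <- composeFields(fg, fl)
    warped <- resampleSlice(image, field, padding = "border")
    list(image = warped, field = field, coefficients = coeffs, localField = fl)
  })
}

#' Generate one co-registered phantom pair with a known deformation
#'
#' Both "modalities" render the same randomly placed anatomy under two
#' distinct monotone intensity mappings plus independent additive noise; the
#' deformed target is the aligned target resampled through the stored field
#' (same resampler, so the closure is exact). Identical seeds give identical
#' output.
#'
#' @param seed integer seed.
#' @param size integer `(H, W)`, at least 32 x 32 (default 128 x 128).
#' @param config a [phantomConfig()].
#' @param deformationSeed optional separate seed for the deformation draw;
#'   by default derived from `seed`. Passing a common value across pairs
#'   yields a domain-consistent (shared) deformation.
#' @return A [PhantomPair-class].
#' @export
generatePhantomPair <- function(seed, size = c(128L, 128L),
                                config = phantomConfig(),
                                deformationSeed = NULL) {
  stopifnot(inherits(config, "phantomConfig"))
  H <- size[1]; W <- size[2]
  if (H < 32 || W < 32) stop("phantom size must be at least 32 x 32")
  dseed <- if (is.null(deformationSeed))
    as.integer((as.numeric(seed) * 7919 + 13) %% 2147483647) else
    as.integer(deformationSeed)
  ab <- with_local_seed(seed, {
    S <- draw_anatomy(H, W, config$nShapes)
    A <- intensity_map_A(S) + stats::rnorm(H * W, sd = config$noiseSd)
    B <- intensity_map_B(S) + stats::rnorm(H * W, sd = config$noiseSd)
    list(A = matrix(A, H, W), B = matrix(B, H, W))
  })
  src <- normalizeSlice(imageSlice(ab$A, domain = "A",
                                   id = sprintf("phantom%04d_A", seed)))
  tgt <- normalizeSlice(imageSlice(ab$B, domain = "B",
                                   id = sprintf("phantom%04d_B", seed)))
  sim <- simulateDomainDeformation(tgt, dseed,
                                   globalMagnitude = config$globalMagnitude,
                                   localMagnitude = config$localMagnitude,
                                   localSigma = config$localSigma)
  new("PhantomPair", source = src, targetAligned = tgt,
      targetDeformed = sim$image, trueDeformation = sim$field,
      seed = as.integer(seed))
}

#' Generate a phantom dataset
#'
#' @param n number of pairs.
#' @param seed base seed; pair `i` uses `seed + i`.
#' @param size slice size `(H, W)`.
#' @param config a [phantomConfig()].
#' @param sharedDeformation if `TRUE` (default) every pair receives the same
#'   deformation draw, emulating a systematic domain-specific deformation; if
#'   `FALSE` each pair gets an independent deformation.
#' @return List of [PhantomPair-class] objects.
#' @export
generatePhantomDataset <- function(n, seed = 0L, size = c(128L, 128L),
                                   config = phantomConfig(),
                                   sharedDeformation = TRUE) {
  stopifnot(n >= 1)
  dseed <- if (sharedDeformation)
    as.integer((as.numeric(seed) * 7919 + 13) %% 2147483647) else NULL
  lapply(seq_len(n), function(i)
    generatePhantomPair(seed + i, size = size, config = config,
                        deformationSeed = dseed))
}

#' Unpaired training set view of a phantom dataset
#'
#' Domain A holds the undeformed source slices; domain B holds the deformed
#' target slices (the co-registered aligned targets are ground truth, not
#' training data). One pair corresponds to one "patient".
#'
#' @param pairs list of [PhantomPair-class].
#' @return A list with elements `A`, `B` (lists of [ImageSlice-class]) and
#'   `patientA`, `patientB` (character vectors).
#' @export
phantomTrainingSet <- function(pairs) {
  list(A = lapply(pairs, function(p) p@source),
       B = lapply(pairs, function(p) p@targetDeformed),
       patientA = sprintf("P%03d", seq_along(pairs)),
       patientB = sprintf("P%03d", seq_along(pairs)))
}

# ---------------------------------------------------------------------------
# dataset I/O
# ---------------------------------------------------------------------------

write_one_image <- function(m, path, format, spacing) {
  if (format == "nifti") {
    img <- RNifti::asNifti(m)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
    c(offset = 0, scale = 1)
  } else {
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    u <- (m - lo) / scale
    if (format == "tiff") tiff::writeTIFF(u, path, bits.per.sample = 16L)
    else png::writePNG(u, path)
    c(offset = lo, scale = scale)
  }
}

read_one_image <- function(path, format, offset, scale) {
  if (format == "nifti") {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1L))
    arr
  } else {
    m <- if (format == "tiff") tiff::readTIFF(path) else png::readPNG(path)
    array(m * scale + offset, dim = c(dim(m)[1:2], 1L))
  }
}

format_ext <- function(format)
  switch(format, nifti = ".nii.gz", tiff = ".tif", png = ".png",
         stop("unsupported format: ", format))

#' Save a phantom dataset to disk with a manifest
#'
#' Writes three images per pair (source, aligned target, deformed target).
#' NIfTI stores the voxel spacing in the header and is lossless; TIFF is
#' written 16-bit after a linear rescale whose parameters are stored in the
#' manifest (quantization <= 1/65535 of the range); PNG is 8-bit with the
#' same rescale bookkeeping (quantization <= 1/255).
#'
#' @param pairs list of [PhantomPair-class].
#' @param dir output directory (created if missing).
#' @param format `"nifti"`, `"tiff"` or `"png"`.
#' @return A [DatasetManifest-class]; also written as `manifest.yaml`.
#' @export
saveDataset <- function(pairs, dir, format = c("nifti", "tiff", "png")) {
  format <- match.arg(format)
  if (length(pairs) == 0) stop("empty dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    imgs <- list(source = p@source, aligned = p@targetAligned,
                 deformed = p@targetDeformed)
    for (role in names(imgs)) {
      sl <- imgs[[role]]
      fn <- sprintf("pair%03d_%s%s", i, role, format_ext(format))
      rs <- write_one_image(pixels(sl), file.path(dir, fn), format, sl@spacing)
      rows[[length(rows) + 1L]] <- data.frame(
        file = fn, domain = domainLabel(sl), patient = sprintf("P%03d", i),
        slice = 1L, role = role, pair = i,
        offset = unname(rs["offset"]), scale = unname(rs["scale"]),
        stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  manifest <- new("DatasetManifest", entries = entries, format = format,
                  root = normalizePath(dir))
  yaml::write_yaml(list(format = format,
                        entries = lapply(seq_len(nrow(entries)), function(r)
                          as.list(entries[r, ]))),
                   file.path(dir, "manifest.yaml"))
  manifest
}

#' Load a dataset from a manifest
#'
#' Reads every referenced image (paths are relative to the manifest
#' location); 3-D NIfTI volumes are split into axial slices. By default each
#' slice is normalized to zero mean and unit standard deviation.
#'
#' @param manifest path to a `manifest.yaml` written by [saveDataset()], or a
#'   [DatasetManifest-class].
#' @param normalize standardize each slice (default TRUE).
#' @return A list with `slices` (list of [ImageSlice-class]) and `manifest`.
#' @export
loadDataset <- function(manifest, normalize = TRUE) {
  if (is(manifest, "DatasetManifest")) {
    entries <- manifest@entries
    root <- manifest@root
    format <- manifest@format
  } else {
    root <- dirname(normalizePath(manifest))
    y <- yaml::read_yaml(manifest)
    format <- y$format
    entries <- do.call(rbind, lapply(y$entries, function(e)
      as.data.frame(e, stringsAsFactors = FALSE)))
  }
  man <- new("DatasetManifest", entries = entries, format = format, root = root)
  slices <- list()
  for (r in seq_len(nrow(entries))) {
    e <- entries[r, ]
    path <- file.path(root, e$file)
    if (!file.exists(path)) stop("missing file: ", path)
    arr <- read_one_image(path, format, e$offset, e$scale)
    for (k in seq_len(dim(arr)[3])) {
      sl <- imageSlice(arr[, , k], domain = e$domain,
                       id = sprintf("%s_s%02d", tools::file_path_sans_ext(e$file), k))
      if (normalize) sl <- normalizeSlice(sl)
      slices[[length(slices) + 1L]] <- sl
    }
  }
  list(slices = slices, manifest = man)
}
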