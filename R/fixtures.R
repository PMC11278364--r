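## Procedural fixtures: stand-ins for the annotated field frame, the
## background-only frames, and the unlabelled "real-domain" frames. All
## randomness flows through R's RNG; public entry points seed it, so every
## fixture is a pure function of (config, seed).

## Band-limited value noise: random grid at wavelength `scale` px,
## bilinearly interpolated up to (H, W). A non-finite or frame-sized scale
## degenerates to a constant field.
valueNoise <- function(H, W, scale) {
  ncH <- if (is.finite(scale)) ceiling(H / scale) else 0
  ncW <- if (is.finite(scale)) ceiling(W / scale) else 0
  gh <- if (ncH >= 1) ncH + 1L else 1L
  gw <- if (ncW >= 1) ncW + 1L else 1L
  g <- matrix(runif(gh * gw), gh, gw)
  u <- if (gh == 1L) rep(1, H) else pmin(1 + (seq_len(H) - 1) / scale, gh)
  v <- if (gw == 1L) rep(1, W) else pmin(1 + (seq_len(W) - 1) / scale, gw)
  i0 <- pmin(floor(u), max(gh - 1L, 1L)); fi <- u - i0
  j0 <- pmin(floor(v), max(gw - 1L, 1L)); fj <- v - j0
  i1 <- pmin(i0 + 1L, gh); j1 <- pmin(j0 + 1L, gw)
  g[i0, j0, drop = FALSE] * outer(1 - fi, 1 - fj) +
    g[i1, j0, drop = FALSE] * outer(fi, 1 - fj) +
    g[i0, j1, drop = FALSE] * outer(1 - fi, fj) +
    g[i1, j1, drop = FALSE] * outer(fi, fj)
}

## Field palette: interpolate brown -> green by one noise field, modulate
## brightness by a second, finer field.
.renderBackground <- function(config) {
  H <- config@imageHeight; W <- config@imageWidth
  mixf <- valueNoise(H, W, config@textureScale)
  bright <- 0.75 + 0.5 * (valueNoise(H, W, config@textureScale / 2) - 0.5)
  brown <- c(0.45, 0.36, 0.22); green <- c(0.30, 0.48, 0.20)
  img <- array(0, c(H, W, 3))
  for (c in 1:3)
    img[, , c] <- (brown[c] * (1 - mixf) + green[c] * mixf) * bright
  clamp01(img)
}

#' Generate a background-only fixture frame
#'
#' A band-limited procedural texture in a green-brown field palette, with no
#' blob (wheat-head) footprints. Deterministic given (config, seed).
#'
#' @param config a [FixtureConfig-class].
#' @param seed integer seed; defaults to the config seed.
#' @return (H, W, 3) image array in \[0, 1\].
#' @export
makeBackground <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(seed)
  .renderBackground(config)
}

## Sample blob parameters for one annotated frame. Blobs whose bounding
## diameter exceeds the frame are rejected and resampled; 100 consecutive
## failures raise an error.
.sampleBlobs <- function(config) {
  k <- sample(seq(config@blobsPerFrame[1], config@blobsPerFrame[2]), 1L)
  H <- config@imageHeight; W <- config@imageWidth
  out <- vector("list", k)
  i <- 0L
  failures <- 0L
  while (i < k) {
    a <- runif(1, config@blobAxes[1], config@blobAxes[2])
    b <- runif(1, config@blobAxes[1], config@blobAxes[2])
    if (2 * max(a, b) > min(H, W)) {
      failures <- failures + 1L
      if (failures >= 100L)
        stop("could not place a blob inside the frame after 100 attempts; ",
             "blobAxes too large for the image dimensions")
      next
    }
    failures <- 0L
    i <- i + 1L
    out[[i]] <- data.frame(
      cy = runif(1, 1, H), cx = runif(1, 1, W), a = a, b = b,
      theta = runif(1, 0, pi))
  }
  if (k == 0L)
    data.frame(cy = numeric(), cx = numeric(), a = numeric(),
               b = numeric(), theta = numeric())
  else do.call(rbind, out)
}

## Pixel-center membership test of one ellipse, evaluated on a local
## bounding box; used both to rasterise and (over the full frame, in tests)
## as the brute-force oracle.
.ellipseFootprint <- function(blob, rows, cols) {
  dy <- outer(rows - blob$cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - blob$cx)
  u <- dy * cos(blob$theta) + dx * sin(blob$theta)
  v <- -dy * sin(blob$theta) + dx * cos(blob$theta)
  (u / blob$a)^2 + (v / blob$b)^2 <= 1
}

.renderAnnotated <- function(config) {
  H <- config@imageHeight; W <- config@imageWidth
  img <- .renderBackground(config)
  blobs <- .sampleBlobs(config)
  mask <- matrix(0L, H, W)
  wheat <- c(0.78, 0.68, 0.38)
  if (nrow(blobs) > 0) for (i in seq_len(nrow(blobs))) {
    bl <- blobs[i, ]
    r <- max(bl$a, bl$b)
    rows <- max(1L, floor(bl$cy - r)):min(H, ceiling(bl$cy + r))
    cols <- max(1L, floor(bl$cx - r)):min(W, ceiling(bl$cx + r))
    inside <- .ellipseFootprint(bl, rows, cols)
    tint <- runif(3, -0.08, 0.08)
    tex <- 0.8 + 0.4 * (valueNoise(length(rows), length(cols), 4) - 0.5)
    for (c in 1:3) {
      patch <- img[rows, cols, c]
      patch[inside] <- clamp01((wheat[c] + tint[c]) * tex)[inside]
      img[rows, cols, c] <- patch
    }
    sub <- mask[rows, cols]
    sub[inside] <- 1L
    mask[rows, cols] <- sub
  }
  list(sample = annotatedSample(clamp01(img), mask), blobs = blobs)
}

#' Generate an annotated fixture frame
#'
#' Background texture plus k textured ellipses (k drawn from
#' `blobsPerFrame`) at random centres, sizes and orientations. The mask is 1
#' exactly on the union of the ellipse footprints, evaluated at pixel
#' centres; blobs may overlap (the mask is their union) and may extend past
#' the frame border, where they are clipped.
#'
#' @param config a [FixtureConfig-class].
#' @param seed integer seed; defaults to the config seed.
#' @param returnBlobs if TRUE, also return the sampled ellipse parameters
#'   (centre, semi-axes, orientation) so the rasterisation can be checked
#'   against an independent per-pixel test.
#' @return an [AnnotatedSample-class], or (with `returnBlobs = TRUE`) a list
#'   with elements `sample` and `blobs`.
#' @export
makeAnnotatedFrame <- function(config, seed = config@seed,
                               returnBlobs = FALSE) {
  validObject(config)
  set.seed(seed)
  res <- .renderAnnotated(config)
  if (returnBlobs) res else res$sample
}

#' Rotate the hue of an RGB image
#'
#' Numeric RGB -> HSV -> RGB round trip with the hue channel shifted by
#' `degrees` (modulo 360), with no 8-bit quantisation.
#'
#' @param image (H, W, 3) array in \[0, 1\].
#' @param degrees hue rotation angle.
#' @return the rotated image, same dimensions and range.
#' @export
hueRotate <- function(image, degrees) {
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsvm <- rgb2hsv(rgb, maxColorValue = 1)
  h <- (hsvm[1, ] + degrees / 360) %% 1
  s <- hsvm[2, ]; v <- hsvm[3, ]
  ## numeric HSV -> RGB (piecewise-linear chroma formulation)
  c <- v * s
  x <- c * (1 - abs((h * 6) %% 2 - 1))
  m <- v - c
  sec <- floor(h * 6) %% 6
  r <- ifelse(sec == 0 | sec == 5, c, ifelse(sec == 1 | sec == 4, x, 0))
  g <- ifelse(sec == 0 | sec == 3, x, ifelse(sec == 1 | sec == 2, c, 0))
  b <- ifelse(sec == 2 | sec == 5, x, ifelse(sec == 3 | sec == 4, c, 0))
  out <- array(0, d)
  out[, , 1] <- r + m; out[, , 2] <- g + m; out[, , 3] <- b + m
  clamp01(out)
}

## Domain shift: hue rotation, Gaussian blur, additive Gaussian noise (the
## noise draws from the current RNG stream).
.applyShift <- function(image, config) {
  out <- image
  if (config@hueShift != 0) out <- hueRotate(out, config@hueShift)
  if (config@blurSigma > 0)
    for (c in 1:3) out[, , c] <- EBImage::gblur(out[, , c], config@blurSigma)
  if (config@noiseSd > 0)
    out <- out + array(rnorm(length(out), 0, config@noiseSd), dim(out))
  clamp01(out)
}

#' Apply the configured domain shift to an image
#'
#' Hue rotation, then Gaussian blur, then additive Gaussian noise (drawn
#' from the current RNG stream). With all three parameters zero this is the
#' identity.
#'
#' @param image (H, W, 3) array in \[0, 1\].
#' @param config a [FixtureConfig-class] providing hueShift, blurSigma,
#'   noiseSd.
#' @return the shifted image.
#' @export
applyDomainShift <- function(image, config) .applyShift(image, config)

#' Generate a real-domain fixture frame
#'
#' An annotated-frame rendering with the configured appearance shift
#' applied, emulating an unlabelled frame of the realistic target domain.
#' The underlying mask is withheld unless `withMask = TRUE` (held-out test
#' frames retain it).
#'
#' @param config a [FixtureConfig-class].
#' @param seed integer seed; defaults to the config seed.
#' @param withMask if TRUE, return an [AnnotatedSample-class] (image plus
#'   mask); otherwise just the image array.
#' @return image array, or AnnotatedSample when `withMask = TRUE`.
#' @export
makeRealDomainFrame <- function(config, seed = config@seed, withMask = FALSE) {
  validObject(config)
  set.seed(seed)
  res <- .renderAnnotated(config)
  shifted <- .applyShift(sampleImage(res$sample), config)
  if (withMask) annotatedSample(shifted, sampleMask(res$sample)) else shifted
}

#' Generate and write a full fixture corpus
#'
#' Writes PNG images (and masks where retained) plus four manifest CSVs:
#' `source` (annotated frames for cutout extraction), `backgrounds`
#' (background-only frames), `real` (unlabelled real-domain frames; empty
#' mask column) and `test` (real-domain frames with retained masks, the
#' internal held-out test set).
#'
#' @param config a [FixtureConfig-class].
#' @param outDir writable output directory (created if absent).
#' @param nSourceFrames annotated source frames to write (>= 1).
#' @return named list of manifests: source, backgrounds, real, test.
#' @export
generateFixtureCorpus <- function(config, outDir, nSourceFrames = 1L) {
  validObject(config)
  stopifnot(nSourceFrames >= 1L)
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  imgDir <- file.path(outDir, "img"); mskDir <- file.path(outDir, "msk")
  dir.create(imgDir, showWarnings = FALSE)
  dir.create(mskDir, showWarnings = FALSE)

  writePair <- function(sample, stem) {
    ip <- file.path(imgDir, paste0(stem, ".png"))
    mp <- file.path(mskDir, paste0(stem, ".png"))
    writeImagePNG(sampleImage(sample), ip)
    writeMaskPNG(sampleMask(sample), mp)
    c(ip, mp)
  }

  srcRows <- lapply(seq_len(nSourceFrames), function(i) {
    s <- makeAnnotatedFrame(config, childSeed(config@seed, i))
    p <- writePair(s, sprintf("source_%04d", i))
    newManifest(p[1], p[2], "source")
  })
  bgRows <- lapply(seq_len(config@nBackgroundFrames), function(i) {
    img <- makeBackground(config, childSeed(config@seed, 1000L + i))
    ip <- file.path(imgDir, sprintf("background_%04d.png", i))
    writeImagePNG(img, ip)
    newManifest(ip, "", "background")
  })
  realRows <- lapply(seq_len(config@nRealFrames), function(i) {
    img <- makeRealDomainFrame(config, childSeed(config@seed, 2000L + i))
    ip <- file.path(imgDir, sprintf("real_%04d.png", i))
    writeImagePNG(img, ip)
    newManifest(ip, "", "train")
  })
  testRows <- lapply(seq_len(config@nTestFrames), function(i) {
    s <- makeRealDomainFrame(config, childSeed(config@seed, 3000L + i),
                             withMask = TRUE)
    p <- writePair(s, sprintf("test_%04d", i))
    newManifest(p[1], p[2], "test")
  })

  bindRows <- function(rows) {
    if (length(rows) == 0)
      newManifest(character(), character(), character())
    else do.call(rbind, rows)
  }
  manifests <- list(source = bindRows(srcRows), backgrounds = bindRows(bgRows),
                    real = bindRows(realRows), test = bindRows(testRows))
  for (nm in names(manifests))
    writeManifest(manifests[[nm]], file.path(outDir, paste0(nm, ".csv")))
  manifests
}
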