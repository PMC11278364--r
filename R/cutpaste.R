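## Cut-and-paste synthesis: extract foreground cutouts from one annotated
## frame and composite them onto background frames, emitting images with
## exact masks. Conventions (contract points): 8-connectivity components,
## tight bounding-box crops, transforms about the cutout centre, bilinear
## RGB resampling, alpha resampled then binarised at 0.5, hard compositing
## (no feathering), mask = union of binarised transformed alphas,
## 0-based (row, col) paste coordinates.

#' Extract foreground cutouts from an annotated sample
#'
#' One [Cutout-class] per 8-connected component of the mask with area >=
#' `minArea` pixels: the patch is the tight bounding-box crop of the image,
#' the alpha is the component's footprint within that crop.
#'
#' @param sample an [AnnotatedSample-class].
#' @param minArea minimal component area in pixels.
#' @param sourcePrefix tag prefix for the cutouts' sourceId.
#' @return list of [Cutout-class] objects (possibly empty).
#' @export
extractCutouts <- function(sample, minArea = 10L, sourcePrefix = "cutout") {
  stopifnot(is(sample, "AnnotatedSample"))
  validObject(sample)
  mask <- sampleMask(sample)
  img <- sampleImage(sample)
  lab <- .cpp_label8(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  n <- max(lab)
  out <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < minArea) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    alpha <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    alpha[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- 1L
    patch <- img[r0:r1, c0:c1, , drop = FALSE]
    cut <- new("Cutout", patch = patch, alpha = alpha,
               sourceId = sprintf("%s_%03d", sourcePrefix, k))
    attr(cut, "bbox") <- c(r0, r1, c0, c1)
    out[[length(out) + 1L]] <- cut
  }
  out
}

## Instance sampling against the current RNG stream (callers seed it).
.sampleInstancesRNG <- function(config, nCutouts, dims) {
  k <- sample(seq(config@headsPerImage[1], config@headsPerImage[2]), 1L)
  data.frame(
    cutoutIndex = if (k > 0) sample(seq_len(nCutouts), k, replace = TRUE)
                  else integer(),
    centerRow = runif(k, 0, dims[1] - 1),
    centerCol = runif(k, 0, dims[2] - 1),
    scale = runif(k, config@scaleRange[1], config@scaleRange[2]),
    rotation = runif(k, config@rotationRange[1], config@rotationRange[2]),
    hflip = runif(k) < 0.5,
    vflip = runif(k) < 0.5
  )
}

#' Sample random paste instances
#'
#' Draws a paste count k uniformly from `headsPerImage`, then for each paste
#' a cutout index, a centre uniform over the frame (0-based row/col), and
#' scale/rotation/flips from the configured ranges.
#'
#' @param config a [SynthesisConfig-class].
#' @param nCutouts number of available cutouts (>= 1; 0 returns an empty
#'   list with a warning).
#' @param dims frame dimensions c(H, W).
#' @param seed integer seed; defaults to the config seed.
#' @return data.frame with columns cutoutIndex, centerRow, centerCol, scale,
#'   rotation, hflip, vflip.
#' @export
sampleInstances <- function(config, nCutouts, dims, seed = config@seed) {
  validObject(config)
  if (nCutouts == 0L) {
    warning("no cutouts available; returning an empty instance list")
    return(data.frame(cutoutIndex = integer(), centerRow = numeric(),
                      centerCol = numeric(), scale = numeric(),
                      rotation = numeric(), hflip = logical(),
                      vflip = logical()))
  }
  set.seed(seed)
  .sampleInstancesRNG(config, nCutouts, dims)
}

## Bilinear sampling of a (h, w) matrix at fractional 0-based coordinates,
## treating everything outside the matrix as `fill`.
.bilinearAt <- function(mat, sr, sc, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  i0 <- floor(sr); j0 <- floor(sc)
  fi <- sr - i0; fj <- sc - j0
  val <- numeric(length(sr))
  for (di in 0:1) for (dj in 0:1) {
    ii <- i0 + di; jj <- j0 + dj
    wgt <- (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
    inside <- ii >= 0 & ii < h & jj >= 0 & jj < w
    v <- rep(fill, length(sr))
    v[inside] <- mat[cbind(ii[inside] + 1L, jj[inside] + 1L)]
    val <- val + wgt * v
  }
  val
}

#' Composite paste instances onto a background
#'
#' Instances are composited in list order: each cutout is scaled/rotated
#' about its centre (bilinear RGB, alpha binarised at 0.5 after resampling),
#' flipped as requested, placed at its 0-based (row, col) centre, clipped at
#' the frame border, and hard-composited (later pastes occlude earlier RGB).
#' The emitted mask is the union of all binarised transformed alphas.
#'
#' @param background (H, W, 3) image array in \[0, 1\].
#' @param cutouts list of [Cutout-class] objects.
#' @param instances data.frame as produced by [sampleInstances()].
#' @return an [AnnotatedSample-class].
#' @export
renderPaste <- function(background, cutouts, instances) {
  stopifnot(length(dim(background)) == 3L, dim(background)[3] == 3L)
  H <- dim(background)[1]; W <- dim(background)[2]
  img <- background
  mask <- matrix(0L, H, W)
  for (t in seq_len(nrow(instances))) {
    inst <- instances[t, ]
    if (inst$cutoutIndex < 1 || inst$cutoutIndex > length(cutouts))
      stop("instance ", t, " references cutout ", inst$cutoutIndex,
           " but only ", length(cutouts), " are available")
    if (inst$scale <= 0) stop("instance scale must be > 0")
    cut <- cutouts[[inst$cutoutIndex]]
    h <- nrow(cut@alpha); w <- ncol(cut@alpha)
    pcr <- (h - 1) / 2; pcc <- (w - 1) / 2     # patch centre, 0-based
    phi <- inst$rotation * pi / 180
    ## conservative output bounding box around the paste centre
    rad <- inst$scale * sqrt(pcr^2 + pcc^2) + 1
    rows <- max(0, ceiling(inst$centerRow - rad)):
            min(H - 1, floor(inst$centerRow + rad))
    cols <- max(0, ceiling(inst$centerCol - rad)):
            min(W - 1, floor(inst$centerCol + rad))
    if (length(rows) == 0 || length(cols) == 0 ||
        rows[1] > rows[length(rows)] || cols[1] > cols[length(cols)]) next
    gr <- rep(rows, times = length(cols)) - inst$centerRow
    gc <- rep(cols, each = length(rows)) - inst$centerCol
    ## inverse map: un-rotate, un-scale, recentre on the patch
    sr <- (cos(phi) * gr + sin(phi) * gc) / inst$scale + pcr
    sc <- (-sin(phi) * gr + cos(phi) * gc) / inst$scale + pcc
    if (isTRUE(inst$hflip)) sc <- (w - 1) - sc
    if (isTRUE(inst$vflip)) sr <- (h - 1) - sr
    aval <- .bilinearAt(cut@alpha * 1.0, sr, sc, fill = 0)
    cover <- aval >= 0.5
    if (!any(cover)) next
    ridx <- rep(rows, times = length(cols)) + 1L
    cidx <- rep(cols, each = length(rows)) + 1L
    sel <- cbind(ridx[cover], cidx[cover])
    for (ch in 1:3) {
      vals <- .bilinearAt(cut@patch[, , ch], sr[cover], sc[cover], fill = 0)
      plane <- img[, , ch]
      plane[sel] <- clamp01(vals)
      img[, , ch] <- plane
    }
    mask[sel] <- 1L
  }
  annotatedSample(img, mask)
}

#' Synthesise a cut-and-paste dataset
#'
#' Writes `nImages` composites (image + exact mask) built from the given
#' cutouts and background frames (backgrounds sampled with replacement), and
#' returns a manifest whose split column assigns the first
#' `round(nImages * trainFraction)` rows to "train" and the rest to "val".
#'
#' @param config a [SynthesisConfig-class].
#' @param cutouts non-empty list of [Cutout-class] objects.
#' @param backgrounds manifest of background frames.
#' @param outDir writable output directory.
#' @return the dataset manifest (also written to `outDir/delta_s.csv`).
#' @export
synthesizeDataset <- function(config, cutouts, backgrounds, outDir) {
  validObject(config)
  if (length(cutouts) == 0L) stop("cannot synthesise from an empty cutout list")
  validateManifest(backgrounds)
  if (nrow(backgrounds) == 0L) stop("background manifest is empty")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  imgDir <- file.path(outDir, "img"); mskDir <- file.path(outDir, "msk")
  dir.create(imgDir, showWarnings = FALSE)
  dir.create(mskDir, showWarnings = FALSE)
  set.seed(config@seed)
  nTrain <- round(config@nImages * config@trainFraction)
  rows <- vector("list", config@nImages)
  ## cache decoded backgrounds (corpora are small; avoids repeated PNG reads)
  bgCache <- new.env(parent = emptyenv())
  for (i in seq_len(config@nImages)) {
    bi <- sample(nrow(backgrounds), 1L)
    key <- as.character(bi)
    if (is.null(bgCache[[key]]))
      bgCache[[key]] <- readImagePNG(backgrounds$image_path[bi])
    bg <- bgCache[[key]]
    inst <- .sampleInstancesRNG(config, length(cutouts), dim(bg)[1:2])
    sm <- renderPaste(bg, cutouts, inst)
    ip <- file.path(imgDir, sprintf("synth_%05d.png", i))
    mp <- file.path(mskDir, sprintf("synth_%05d.png", i))
    writeImagePNG(sampleImage(sm), ip)
    writeMaskPNG(sampleMask(sm), mp)
    rows[[i]] <- newManifest(ip, mp, if (i <= nTrain) "train" else "val")
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(outDir, "delta_s.csv"))
  manifest
}
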