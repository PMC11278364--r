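## Mask-preserving CycleGAN. The source domain S carries 4-channel samples
## (image in [-1, 1] plus mask mapped {0 -> -1, 1 -> +1}); the target
## domain R carries 3-channel realistic images. Because the S-side cycle
## loss is an equal-weight L1 over all four channels, the mask must be
## recreated at the end of the S -> R -> S cycle, which is what preserves
## annotations through translation. The source discriminator judges the
## full image+mask concatenation.

#' Build a 4-channel source-domain sample from image and mask
#'
#' @param image (H, W, 3) array in \[0, 1\].
#' @param mask (H, W) matrix in {0, 1}.
#' @return a [DomainSampleS-class] with channels in \[-1, 1\].
#' @export
domainSampleS <- function(image, mask) {
  stopifnot(identical(dim(image)[1:2], dim(mask)))
  ch <- array(0, c(dim(mask), 4L))
  ch[, , 1:3] <- image * 2 - 1
  ch[, , 4] <- matrix(as.numeric(mask) * 2 - 1, nrow(mask), ncol(mask))
  new("DomainSampleS", channels = ch)
}

#' Build a 3-channel target-domain sample from an image
#'
#' @param image (H, W, 3) array in \[0, 1\].
#' @return a [DomainSampleR-class] with channels in \[-1, 1\].
#' @export
domainSampleR <- function(image) {
  new("DomainSampleR", channels = image * 2 - 1)
}

#' Recover a \[0, 1\] image from target-domain channels
#'
#' @param sample a [DomainSampleR-class] (or a plain (H, W, 3) array in
#'   \[-1, 1\]).
#' @return (H, W, 3) image array in \[0, 1\].
#' @export
domainImage <- function(sample) {
  ch <- if (is(sample, "DomainSampleR") || is(sample, "DomainSampleS"))
    sample@channels else sample
  clamp01((ch[, , 1:3, drop = FALSE] + 1) / 2)
}

.channelsOf <- function(x) {
  if (is(x, "DomainSampleS") || is(x, "DomainSampleR")) x@channels else x
}

#' Least-squares adversarial loss
#'
#' Mean squared deviation of a discriminator score map from 1 (real target)
#' or 0 (fake target).
#'
#' @param discMap score array/matrix from a patch discriminator.
#' @param targetIsReal logical target label.
#' @return non-negative scalar.
#' @export
adversarialLoss <- function(discMap, targetIsReal) {
  if (!all(is.finite(discMap))) stop("discriminator scores must be finite")
  target <- if (isTRUE(targetIsReal)) 1 else 0
  mean((discMap - target)^2)
}

## gradient of adversarialLoss w.r.t. the score map
.advGrad <- function(discMap, targetIsReal) {
  target <- if (isTRUE(targetIsReal)) 1 else 0
  2 * (discMap - target) / length(discMap)
}

#' Source-domain cycle-consistency loss
#'
#' Mean absolute difference over all four channels — the mask channel is
#' weighted equally with the image channels, which is the mechanism that
#' forces mask recreation through the cycle.
#'
#' @param original,reconstructed [DomainSampleS-class] objects (or (H, W, 4)
#'   arrays) of matching dimensions.
#' @return non-negative scalar.
#' @export
cycleLossS <- function(original, reconstructed) {
  a <- .channelsOf(original); b <- .channelsOf(reconstructed)
  if (!identical(dim(a), dim(b))) stop("dimension mismatch in cycle loss")
  if (dim(a)[3] != 4L) stop("source-domain samples must have 4 channels")
  mean(abs(a - b))
}

#' Target-domain cycle-consistency loss
#'
#' Mean absolute difference over the three image channels for the reverse
#' cycle R -> S -> R.
#'
#' @param original,reconstructed [DomainSampleR-class] objects (or (H, W, 3)
#'   arrays) of matching dimensions.
#' @return non-negative scalar.
#' @export
cycleLossR <- function(original, reconstructed) {
  a <- .channelsOf(original); b <- .channelsOf(reconstructed)
  if (!identical(dim(a), dim(b))) stop("dimension mismatch in cycle loss")
  if (dim(a)[3] != 3L) stop("target-domain samples must have 3 channels")
  mean(abs(a - b))
}

## subgradient of mean|rec - orig| w.r.t. rec (sign(0) = 0)
.l1Grad <- function(orig, rec) sign(rec - orig) / length(rec)

#' Initialise a mask-preserving CycleGAN
#'
#' Builds the two generators (S(4ch) -> R(3ch), R(3ch) -> S(4ch)), the two
#' patch discriminators, their Adam optimizers and the replay buffers, with
#' parameters drawn under the config seed.
#'
#' @param config a [GanConfig-class].
#' @return a [GanState-class].
#' @export
buildGan <- function(config) {
  validObject(config)
  set.seed(config@seed)
  base <- config@baseChannels; nres <- config@nResBlocks
  gSR <- resnetGenerator(4L, 3L, base, nres)
  gRS <- resnetGenerator(3L, 4L, base, nres)
  dS <- patchDiscriminator(4L, base)
  dR <- patchDiscriminator(3L, base)
  pG <- c(nnParams(gSR), nnParams(gRS))
  pD <- c(nnParams(dS), nnParams(dR))
  optG <- optAdam(pG, config@learningRate, config@beta1, config@beta2)
  optD <- optAdam(pD, config@learningRate, config@beta1, config@beta2)
  buffers <- new.env(parent = emptyenv())
  buffers$S <- list(); buffers$R <- list()
  new("GanState", gSR = gSR, gRS = gRS, dS = dS, dR = dR,
      optG = optG, optD = optD, buffers = buffers, config = config,
      epoch = 0L,
      lossHistory = data.frame(step = integer(), adv_sr = numeric(),
                               adv_rs = numeric(), cycle_s = numeric(),
                               cycle_r = numeric(), d_s = numeric(),
                               d_r = numeric(), g_total = numeric()))
}

## replay buffer: keep up to `cap` past fakes; with probability 1/2 swap the
## incoming fake for a stored one (stabilises discriminator updates)
.bufferDraw <- function(buffers, which, fake, cap) {
  pool <- buffers[[which]]
  if (length(pool) < cap) {
    pool[[length(pool) + 1L]] <- fake
    buffers[[which]] <- pool
    return(fake)
  }
  if (runif(1) < 0.5) {
    i <- sample(length(pool), 1L)
    out <- pool[[i]]
    pool[[i]] <- fake
    buffers[[which]] <- pool
    out
  } else fake
}

#' Run one optimisation step of the modified CycleGAN
#'
#' Executes both cycles — S -> R -> S and R -> S -> R — for every pair in
#' the batch. The generator objective is the sum of the two least-squares
#' adversarial terms and `lambdaCycle` times the two L1 cycle losses (the
#' S-side loss covering all four channels); gradients are accumulated over
#' the batch and applied in one Adam step. The discriminators are then
#' updated on real samples and on fakes drawn through the replay buffers.
#'
#' @param state a [GanState-class].
#' @param batchS list of [DomainSampleS-class] (or a single sample).
#' @param batchR list of [DomainSampleR-class] (or a single sample).
#' @return list with elements `state` (updated) and `losses` (named numeric:
#'   adv_sr, adv_rs, cycle_s, cycle_r, d_s, d_r, g_total).
#' @export
trainingStep <- function(state, batchS, batchR) {
  if (is(batchS, "DomainSampleS")) batchS <- list(batchS)
  if (is(batchR, "DomainSampleR")) batchR <- list(batchR)
  if (length(batchS) == 0L || length(batchR) == 0L)
    stop("batches must be non-empty")
  n <- max(length(batchS), length(batchR))
  lam <- state@config@lambdaCycle
  gSR <- state@gSR; gRS <- state@gRS; dS <- state@dS; dR <- state@dR

  acc <- c(adv_sr = 0, adv_rs = 0, cycle_s = 0, cycle_r = 0,
           d_s = 0, d_r = 0, g_total = 0)
  fakesR <- vector("list", n); fakesS <- vector("list", n)

  ## ---- generator update ----
  zeroGrads(state@optG$params)
  for (i in seq_len(n)) {
    xs <- .channelsOf(batchS[[(i - 1L) %% length(batchS) + 1L]])
    yr <- .channelsOf(batchR[[(i - 1L) %% length(batchR) + 1L]])
    if (dim(xs)[3] != 4L || dim(yr)[3] != 3L)
      stop("channel arity mismatch: S samples need 4 channels, R samples 3")
    ## forward order: gSR(xs), gRS(yr), gRS(fakeR), gSR(fakeS), dR, dS
    fakeR <- netForward(gSR, xs)
    fakeS <- netForward(gRS, yr)
    recS <- netForward(gRS, fakeR)
    recR <- netForward(gSR, fakeS)
    dRmap <- netForward(dR, fakeR)
    dSmap <- netForward(dS, fakeS)
    lAdvSR <- adversarialLoss(dRmap, TRUE)
    lAdvRS <- adversarialLoss(dSmap, TRUE)
    lCycS <- cycleLossS(xs, recS)
    lCycR <- cycleLossR(yr, recR)
    ## backward in reverse forward order (caches pop as stacks)
    gFakeS_adv <- netBackward(dS, .advGrad(dSmap, TRUE))
    gFakeR_adv <- netBackward(dR, .advGrad(dRmap, TRUE))
    gFakeS_cyc <- netBackward(gSR, lam * .l1Grad(yr, recR))
    gFakeR_cyc <- netBackward(gRS, lam * .l1Grad(xs, recS))
    netBackward(gRS, gFakeS_adv + gFakeS_cyc)
    netBackward(gSR, gFakeR_adv + gFakeR_cyc)
    fakesR[[i]] <- fakeR; fakesS[[i]] <- fakeS
    acc["adv_sr"] <- acc["adv_sr"] + lAdvSR
    acc["adv_rs"] <- acc["adv_rs"] + lAdvRS
    acc["cycle_s"] <- acc["cycle_s"] + lCycS
    acc["cycle_r"] <- acc["cycle_r"] + lCycR
  }
  if (n > 1L)                                   # mean gradient over the batch
    for (p in state@optG$params) p$env[[p$g]] <- p$env[[p$g]] / n
  optStep(state@optG)

  ## ---- discriminator update (fakes detached, drawn via replay buffer) ----
  zeroGrads(state@optD$params)
  cap <- state@config@replayBufferSize
  for (i in seq_len(n)) {
    xs <- .channelsOf(batchS[[(i - 1L) %% length(batchS) + 1L]])
    yr <- .channelsOf(batchR[[(i - 1L) %% length(batchR) + 1L]])
    bufR <- .bufferDraw(state@buffers, "R", fakesR[[i]], cap)
    bufS <- .bufferDraw(state@buffers, "S", fakesS[[i]], cap)
    dRreal <- netForward(dR, yr)
    dRfake <- netForward(dR, bufR)
    dSreal <- netForward(dS, xs)
    dSfake <- netForward(dS, bufS)
    lDR <- 0.5 * (adversarialLoss(dRreal, TRUE) + adversarialLoss(dRfake, FALSE))
    lDS <- 0.5 * (adversarialLoss(dSreal, TRUE) + adversarialLoss(dSfake, FALSE))
    netBackward(dS, 0.5 * .advGrad(dSfake, FALSE))
    netBackward(dS, 0.5 * .advGrad(dSreal, TRUE))
    netBackward(dR, 0.5 * .advGrad(dRfake, FALSE))
    netBackward(dR, 0.5 * .advGrad(dRreal, TRUE))
    acc["d_s"] <- acc["d_s"] + lDS
    acc["d_r"] <- acc["d_r"] + lDR
  }
  if (n > 1L)
    for (p in state@optD$params) p$env[[p$g]] <- p$env[[p$g]] / n
  optStep(state@optD)

  losses <- acc / n
  losses["g_total"] <- losses["adv_sr"] + losses["adv_rs"] +
    lam * (losses["cycle_s"] + losses["cycle_r"])
  hist <- state@lossHistory
  hist[nrow(hist) + 1L, ] <- c(nrow(hist) + 1L, losses[c(
    "adv_sr", "adv_rs", "cycle_s", "cycle_r", "d_s", "d_r", "g_total")])
  state@lossHistory <- hist
  list(state = state, losses = losses)
}

.randomCrop <- function(arr, size) {
  d <- dim(arr)
  if (d[1] == size && d[2] == size) return(arr)
  if (d[1] < size || d[2] < size)
    stop("image (", d[1], "x", d[2], ") smaller than crop size ", size)
  r0 <- sample(d[1] - size + 1L, 1L)
  c0 <- sample(d[2] - size + 1L, 1L)
  arr[r0:(r0 + size - 1L), c0:(c0 + size - 1L), , drop = FALSE]
}

.loadDomainS <- function(row) {
  domainSampleS(readImagePNG(row$image_path), readMaskPNG(row$mask_path))
}

#' Train the modified CycleGAN
#'
#' Runs `config@epochs` epochs over the annotated source manifest, pairing
#' every source sample with a random real-domain sample per step (crops are
#' taken when frames exceed `cropSize`). Optionally writes one checkpoint
#' per epoch (`gan_epoch{N}.ckpt`, an RDS file).
#'
#' @param config a [GanConfig-class].
#' @param manifestS manifest of annotated source samples (masks required).
#' @param manifestR manifest of unlabelled real-domain images.
#' @param outDir optional checkpoint directory.
#' @return the trained [GanState-class].
#' @export
trainGan <- function(config, manifestS, manifestR, outDir = NULL) {
  validateManifest(manifestS, requireMasks = TRUE)
  validateManifest(manifestR)
  if (nrow(manifestS) == 0L || nrow(manifestR) == 0L)
    stop("both manifests must be non-empty")
  state <- buildGan(config)                    # seeds the RNG
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  sCache <- lapply(seq_len(nrow(manifestS)),
                   function(i) .loadDomainS(manifestS[i, ]))
  rCache <- lapply(manifestR$image_path,
                   function(p) domainSampleR(readImagePNG(p)))
  size <- config@cropSize
  ## reconstruction warm-start: fit each generator's image channels to its
  ## input so the adversarial phase starts from a positively correlated
  ## mapping (see ganConfig)
  for (k in seq_len(if (config@epochs > 0L) config@warmupSteps else 0L)) {
    xs <- .randomCrop(sCache[[sample(length(sCache), 1L)]]@channels, size)
    yr <- .randomCrop(rCache[[sample(length(rCache), 1L)]]@channels, size)
    zeroGrads(state@optG$params)
    outR <- netForward(state@gSR, xs)
    netBackward(state@gSR, .l1Grad(xs[, , 1:3, drop = FALSE], outR))
    outS <- netForward(state@gRS, yr)
    g4 <- array(0, dim(outS))                  # mask channel unconstrained
    g4[, , 1:3] <- .l1Grad(yr, outS[, , 1:3, drop = FALSE])
    netBackward(state@gRS, g4)
    optStep(state@optG)
  }
  for (e in seq_len(config@epochs)) {
    ord <- sample(length(sCache))
    for (si in ord) {
      xs <- .randomCrop(sCache[[si]]@channels, size)
      yr <- .randomCrop(rCache[[sample(length(rCache), 1L)]]@channels, size)
      res <- trainingStep(state,
                          new("DomainSampleS", channels = xs),
                          new("DomainSampleR", channels = yr))
      state <- res$state
    }
    state@epoch <- e
    if (!is.null(outDir))
      saveRDS(state, file.path(outDir, sprintf("gan_epoch%d.ckpt", e)))
  }
  state
}

#' Translate a source-domain sample to the realistic domain
#'
#' Applies the trained generator G(S -> R); the mask channel informs the
#' translation but is not part of the output.
#'
#' @param state a [GanState-class].
#' @param sample a [DomainSampleS-class].
#' @return a [DomainSampleR-class] with the same spatial dimensions.
#' @export
translateSample <- function(state, sample) {
  ch <- .channelsOf(sample)
  if (dim(ch)[3] != 4L) stop("expected a 4-channel source-domain sample")
  out <- netForward(state@gSR, ch, train = FALSE)
  new("DomainSampleR", channels = out)
}

#' Recreate a source-domain sample from a realistic image
#'
#' Applies the reverse generator G(R -> S), producing image channels plus a
#' mask channel. With `binarizeMask = TRUE` the mask channel is thresholded
#' at 0 (the midpoint of \[-1, 1\]); exact ties go to foreground.
#'
#' @param state a [GanState-class].
#' @param sample a [DomainSampleR-class].
#' @param binarizeMask logical; binarize the mask channel.
#' @return a [DomainSampleS-class].
#' @export
recreateS <- function(state, sample, binarizeMask = FALSE) {
  ch <- .channelsOf(sample)
  if (dim(ch)[3] != 3L) stop("expected a 3-channel target-domain sample")
  out <- netForward(state@gRS, ch, train = FALSE)
  if (binarizeMask)
    out[, , 4] <- ifelse(out[, , 4] >= 0, 1, -1)
  new("DomainSampleS", channels = out)
}

#' Translate an annotated dataset through the trained generator
#'
#' For every row of the source manifest, writes the translated image and
#' copies the original mask file byte-for-byte (the architecture never
#' rewrites the annotation of a translated sample). Row order and splits
#' are preserved.
#'
#' @param state a trained [GanState-class].
#' @param manifestS manifest of annotated source samples.
#' @param outDir writable output directory.
#' @return the translated-dataset manifest (also written to
#'   `outDir/delta_gan.csv`).
#' @export
buildGanDataset <- function(state, manifestS, outDir) {
  validateManifest(manifestS, requireMasks = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  imgDir <- file.path(outDir, "img"); mskDir <- file.path(outDir, "msk")
  dir.create(imgDir, showWarnings = FALSE)
  dir.create(mskDir, showWarnings = FALSE)
  rows <- vector("list", nrow(manifestS))
  for (i in seq_len(nrow(manifestS))) {
    row <- manifestS[i, ]
    if (!file.exists(row$image_path) || !file.exists(row$mask_path))
      stop("missing input files for manifest row ", i)
    s <- .loadDomainS(row)
    tr <- translateSample(state, s)
    ip <- file.path(imgDir, sprintf("gan_%05d.png", i))
    mp <- file.path(mskDir, sprintf("gan_%05d.png", i))
    writeImagePNG(domainImage(tr), ip)
    file.copy(row$mask_path, mp, overwrite = TRUE)
    rows[[i]] <- newManifest(ip, mp, row$split)
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(outDir, "delta_gan.csv"))
  manifest
}
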