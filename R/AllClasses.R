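## Central S4 containers. Images are (H, W, 3) double arrays in [0, 1];
## masks are (H, W) integer matrices in {0, 1}. GAN-domain tensors are
## (H, W, C) arrays in [-1, 1] (C = 4 for the annotated source domain S:
## three image channels plus the mask mapped {0 -> -1, 1 -> +1}; C = 3 for
## the realistic target domain R).

## ---- fixtures --------------------------------------------------------------

#' FixtureConfig: parameters of the procedural fixture generator
#'
#' Describes the synthetic stand-ins for a wheat-field study: an annotated
#' source frame (textured background plus textured elliptical blobs with an
#' exact mask), background-only frames, and "real-domain" frames that are the
#' same content under a global appearance shift (hue rotation, Gaussian blur,
#' additive noise).
#'
#' @slot seed integer; master seed for all fixture randomness.
#' @slot imageHeight,imageWidth frame size in pixels (>= 32).
#' @slot nBackgroundFrames,nRealFrames,nTestFrames corpus sizes (>= 0).
#' @slot blobsPerFrame integer range \[min, max\] of blobs per annotated frame.
#' @slot blobAxes pixel range for ellipse semi-axes (min >= 2).
#' @slot textureScale spatial wavelength (px) of the procedural value noise.
#' @slot hueShift domain-shift hue rotation in degrees.
#' @slot blurSigma domain-shift Gaussian blur sigma in pixels.
#' @slot noiseSd domain-shift additive noise sd, intensity units in \[0, 1\].
#' @export
setClass("FixtureConfig", representation(
  seed = "integer",
  imageHeight = "integer", imageWidth = "integer",
  nBackgroundFrames = "integer", nRealFrames = "integer",
  nTestFrames = "integer",
  blobsPerFrame = "integer", blobAxes = "numeric",
  textureScale = "numeric",
  hueShift = "numeric", blurSigma = "numeric", noiseSd = "numeric"
))

setValidity("FixtureConfig", function(object) {
  msgs <- character()
  if (object@imageHeight < 32L || object@imageWidth < 32L)
    msgs <- c(msgs, "image dimensions must be >= 32 px")
  if (any(c(object@nBackgroundFrames, object@nRealFrames,
            object@nTestFrames) < 0L))
    msgs <- c(msgs, "frame counts must be >= 0")
  if (length(object@blobsPerFrame) != 2L ||
      any(object@blobsPerFrame < 0L) || diff(object@blobsPerFrame) < 0L)
    msgs <- c(msgs, "blobsPerFrame must be a non-decreasing [min, max] pair")
  if (length(object@blobAxes) != 2L || object@blobAxes[1] < 2 ||
      diff(object@blobAxes) < 0)
    msgs <- c(msgs, "blobAxes must be [min, max] with min >= 2 px")
  if (object@textureScale <= 0) msgs <- c(msgs, "textureScale must be > 0")
  if (object@blurSigma < 0 || object@noiseSd < 0)
    msgs <- c(msgs, "blurSigma and noiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FixtureConfig
#'
#' Defaults describe the study conditions the fixtures emulate: 256 x 256
#' frames, 12 background frames (one per background video plus one), 40
#' unlabelled real-domain frames, 20 held-out annotated test frames, 6-14
#' wheat-head-sized blobs per annotated frame, and an appearance shift
#' (60 degrees of hue, 1 px blur, 2% noise) strong enough that a segmenter
#' trained on source-domain renderings degrades substantially on the real
#' domain — the gap the translation stage exists to close.
#'
#' @param seed integer master seed.
#' @param imageHeight,imageWidth frame size in pixels.
#' @param nBackgroundFrames,nRealFrames,nTestFrames corpus sizes.
#' @param blobsPerFrame length-2 integer range.
#' @param blobAxes length-2 range of ellipse semi-axes in pixels.
#' @param textureScale texture wavelength in pixels.
#' @param hueShift,blurSigma,noiseSd domain-shift strength.
#' @return a [FixtureConfig-class] object.
#' @export
fixtureConfig <- function(seed = 1L, imageHeight = 256L, imageWidth = 256L,
                          nBackgroundFrames = 12L, nRealFrames = 40L,
                          nTestFrames = 20L, blobsPerFrame = c(6L, 14L),
                          blobAxes = c(6, 18), textureScale = 16,
                          hueShift = 60, blurSigma = 1, noiseSd = 0.02) {
  new("FixtureConfig", seed = as.integer(seed),
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      nBackgroundFrames = as.integer(nBackgroundFrames),
      nRealFrames = as.integer(nRealFrames), nTestFrames = as.integer(nTestFrames),
      blobsPerFrame = as.integer(blobsPerFrame), blobAxes = as.numeric(blobAxes),
      textureScale = as.numeric(textureScale), hueShift = as.numeric(hueShift),
      blurSigma = as.numeric(blurSigma), noiseSd = as.numeric(noiseSd))
}

setMethod("show", "FixtureConfig", function(object) {
  cat("FixtureConfig:", object@imageHeight, "x", object@imageWidth,
      "px | seed", object@seed, "\n",
      " backgrounds:", object@nBackgroundFrames,
      " real:", object@nRealFrames, " test:", object@nTestFrames, "\n",
      " blobs/frame:", paste(object@blobsPerFrame, collapse = "-"),
      " axes:", paste(object@blobAxes, collapse = "-"), "px\n",
      " domain shift: hue", object@hueShift, "deg, blur",
      object@blurSigma, "px, noise sd", object@noiseSd, "\n")
})

## ---- annotated samples and cutouts ----------------------------------------

#' AnnotatedSample: an RGB image paired with its binary segmentation mask
#'
#' The unit flowing through every pipeline stage: image values in \[0, 1\],
#' mask strictly binary with identical spatial dimensions.
#'
#' @slot image (H, W, 3) double array in \[0, 1\].
#' @slot mask (H, W) integer matrix in {0, 1}.
#' @export
setClass("AnnotatedSample", representation(image = "array", mask = "matrix"))

setValidity("AnnotatedSample", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) return("image must be an (H, W, 3) array")
  if (!identical(dim(object@mask), d[1:2]))
    return("mask dimensions must equal image dimensions")
  if (!all(object@mask %in% c(0L, 1L))) return("mask must be strictly binary")
  if (min(object@image) < 0 || max(object@image) > 1)
    return("image values must lie in [0, 1]")
  TRUE
})

#' Construct an AnnotatedSample
#' @param image (H, W, 3) array in \[0, 1\].
#' @param mask (H, W) matrix in {0, 1}.
#' @return an [AnnotatedSample-class] object.
#' @export
annotatedSample <- function(image, mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  new("AnnotatedSample", image = image, mask = m)
}

#' @describeIn annotatedSample image accessor.
#' @param x an AnnotatedSample.
#' @export
sampleImage <- function(x) x@image

#' @describeIn annotatedSample mask accessor.
#' @export
sampleMask <- function(x) x@mask

setMethod("show", "AnnotatedSample", function(object) {
  d <- dim(object@image)
  cat("AnnotatedSample:", d[1], "x", d[2], "px,",
      sum(object@mask), "foreground px (",
      round(100 * mean(object@mask), 1), "% )\n")
})

#' Cutout: a cropped foreground patch with per-pixel alpha
#'
#' The paste currency of cut-and-paste synthesis: a tight bounding-box crop
#' of one connected mask component, with the component footprint as a binary
#' alpha channel.
#'
#' @slot patch (h, w, 3) double array in \[0, 1\].
#' @slot alpha (h, w) integer matrix in {0, 1}.
#' @slot sourceId character tag naming the component's origin.
#' @export
setClass("Cutout", representation(patch = "array", alpha = "matrix",
                                  sourceId = "character"))

setValidity("Cutout", function(object) {
  d <- dim(object@patch)
  if (length(d) != 3L || d[3] != 3L) return("patch must be (h, w, 3)")
  if (!identical(dim(object@alpha), d[1:2]))
    return("alpha dimensions must equal patch dimensions")
  if (!all(object@alpha %in% c(0L, 1L))) return("alpha must be binary")
  if (sum(object@alpha) < 1L) return("alpha must cover at least one pixel")
  TRUE
})

setMethod("show", "Cutout", function(object) {
  d <- dim(object@patch)
  cat("Cutout", object@sourceId, ":", d[1], "x", d[2], "px,",
      sum(object@alpha), "alpha px\n")
})

## ---- synthesis configuration ----------------------------------------------

#' SynthesisConfig: parameters of cut-and-paste dataset synthesis
#'
#' Defaults mirror the study's synthetic dataset: 11,000 composites with a
#' 10,000/1,000 train/validation split. Geometric jitter ranges are
#' config-exposed (the study does not publish them).
#'
#' @slot nImages number of composites to synthesise.
#' @slot headsPerImage integer range of pastes per composite.
#' @slot scaleRange,rotationRange continuous jitter ranges (unitless, degrees).
#' @slot trainFraction proportion of rows assigned to the train split.
#' @slot seed integer seed.
#' @export
setClass("SynthesisConfig", representation(
  nImages = "integer", headsPerImage = "integer",
  scaleRange = "numeric", rotationRange = "numeric",
  trainFraction = "numeric", seed = "integer"
))

setValidity("SynthesisConfig", function(object) {
  msgs <- character()
  if (object@nImages < 1L) msgs <- c(msgs, "nImages must be >= 1")
  if (length(object@headsPerImage) != 2L || any(object@headsPerImage < 0L) ||
      diff(object@headsPerImage) < 0L)
    msgs <- c(msgs, "headsPerImage must be a [min, max] pair")
  if (length(object@scaleRange) != 2L || object@scaleRange[1] <= 0 ||
      diff(object@scaleRange) < 0)
    msgs <- c(msgs, "scaleRange must be positive and non-decreasing")
  if (length(object@rotationRange) != 2L || diff(object@rotationRange) < 0)
    msgs <- c(msgs, "rotationRange must be non-decreasing")
  if (object@trainFraction <= 0 || object@trainFraction > 1)
    msgs <- c(msgs, "trainFraction must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SynthesisConfig
#' @param nImages composites to synthesise (study value: 11000).
#' @param headsPerImage integer range of pastes per composite.
#' @param scaleRange,rotationRange jitter ranges.
#' @param trainFraction train split proportion (study value: 10000/11000).
#' @param seed integer seed.
#' @return a [SynthesisConfig-class] object.
#' @export
synthesisConfig <- function(nImages = 11000L, headsPerImage = c(10L, 30L),
                            scaleRange = c(0.7, 1.3),
                            rotationRange = c(-180, 180),
                            trainFraction = 10000 / 11000, seed = 1L) {
  new("SynthesisConfig", nImages = as.integer(nImages),
      headsPerImage = as.integer(headsPerImage),
      scaleRange = as.numeric(scaleRange),
      rotationRange = as.numeric(rotationRange),
      trainFraction = as.numeric(trainFraction), seed = as.integer(seed))
}

## ---- GAN domain samples and state -----------------------------------------

#' DomainSampleS: 4-channel sample of the annotated source domain
#'
#' Concatenation of a normalised image and its mask: channels 1-3 are the
#' image in \[-1, 1\], channel 4 is the mask mapped {0 -> -1, 1 -> +1}.
#'
#' @slot channels (H, W, 4) array in \[-1, 1\].
#' @export
setClass("DomainSampleS", representation(channels = "array"))

setValidity("DomainSampleS", function(object) {
  d <- dim(object@channels)
  if (length(d) != 3L || d[3] != 4L) return("channels must be (H, W, 4)")
  if (min(object@channels) < -1 - 1e-9 || max(object@channels) > 1 + 1e-9)
    return("values must lie in [-1, 1]")
  TRUE
})

#' DomainSampleR: 3-channel sample of the realistic target domain
#'
#' @slot channels (H, W, 3) array in \[-1, 1\].
#' @export
setClass("DomainSampleR", representation(channels = "array"))

setValidity("DomainSampleR", function(object) {
  d <- dim(object@channels)
  if (length(d) != 3L || d[3] != 3L) return("channels must be (H, W, 3)")
  if (min(object@channels) < -1 - 1e-9 || max(object@channels) > 1 + 1e-9)
    return("values must lie in [-1, 1]")
  TRUE
})

#' GanConfig: training configuration of the mask-preserving CycleGAN
#'
#' Defaults follow the study recipe where stated (60 epochs, Adam at
#' lr 2e-4) and the canonical unpaired-translation defaults elsewhere
#' (betas (0.5, 0.999), least-squares adversarial loss, cycle weight 10,
#' replay buffer of 50).
#'
#' @slot epochs training epochs (study value 60).
#' @slot learningRate Adam learning rate (study value 2e-4).
#' @slot beta1,beta2 Adam moment decay rates.
#' @slot lambdaCycle weight of the L1 cycle losses.
#' @slot replayBufferSize discriminator replay pool size.
#' @slot warmupSteps reconstruction warm-start steps before adversarial
#'   training (see [ganConfig()]).
#' @slot cropSize training crop in pixels.
#' @slot baseChannels,nResBlocks generator capacity knobs.
#' @slot seed integer seed.
#' @export
setClass("GanConfig", representation(
  epochs = "integer", learningRate = "numeric",
  beta1 = "numeric", beta2 = "numeric",
  lambdaCycle = "numeric", replayBufferSize = "integer",
  warmupSteps = "integer",
  cropSize = "integer", baseChannels = "integer", nResBlocks = "integer",
  seed = "integer"
))

setValidity("GanConfig", function(object) {
  msgs <- character()
  if (object@epochs < 0L) msgs <- c(msgs, "epochs must be >= 0")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@lambdaCycle < 0) msgs <- c(msgs, "lambdaCycle must be >= 0")
  if (object@replayBufferSize < 1L)
    msgs <- c(msgs, "replayBufferSize must be >= 1")
  if (object@warmupSteps < 0L) msgs <- c(msgs, "warmupSteps must be >= 0")
  if (object@baseChannels < 1L || object@nResBlocks < 0L)
    msgs <- c(msgs, "baseChannels >= 1 and nResBlocks >= 0 required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GanConfig
#' @param epochs training epochs.
#' @param learningRate Adam learning rate.
#' @param beta1,beta2 Adam betas.
#' @param lambdaCycle cycle-loss weight.
#' @param replayBufferSize discriminator replay pool size.
#' @param warmupSteps reconstruction warm-start steps run before the
#'   adversarial epochs: each generator's image channels are fitted by L1 to
#'   reproduce its own input. This anchors the initial translation to be
#'   positively correlated with its input; without it, the unconditioned
#'   adversarial objective can settle into a stable contrast-inverted
#'   mapping (foreground rendered darker than background while the real
#'   domain has it brighter), which satisfies the cycle loss perfectly and
#'   poisons every dataset translated afterwards. 0 disables.
#' @param cropSize training crop (px); 256 for full runs, 64 for desk-scale.
#' @param baseChannels,nResBlocks generator width and residual depth.
#' @param seed integer seed.
#' @return a [GanConfig-class] object.
#' @export
ganConfig <- function(epochs = 60L, learningRate = 2e-4,
                      beta1 = 0.5, beta2 = 0.999, lambdaCycle = 10,
                      replayBufferSize = 50L, warmupSteps = 100L,
                      cropSize = 256L, baseChannels = 32L, nResBlocks = 6L,
                      seed = 1L) {
  new("GanConfig", epochs = as.integer(epochs),
      learningRate = as.numeric(learningRate),
      beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
      lambdaCycle = as.numeric(lambdaCycle),
      replayBufferSize = as.integer(replayBufferSize),
      warmupSteps = as.integer(warmupSteps),
      cropSize = as.integer(cropSize), baseChannels = as.integer(baseChannels),
      nResBlocks = as.integer(nResBlocks), seed = as.integer(seed))
}

#' GanState: parameters and training state of the modified CycleGAN
#'
#' Holds the two generators (source-to-real maps 4 channels to 3; real-to-
#' source maps 3 back to 4), the two patch discriminators (the source-domain
#' discriminator judges the full image+mask concatenation), their optimizers,
#' the replay buffers, the epoch counter and the per-step loss history.
#' Networks and optimizers are mutable environments.
#'
#' @slot gSR,gRS,dS,dR network environments.
#' @slot optG,optD Adam optimizer environments.
#' @slot buffers environment holding the replay pools.
#' @slot config the [GanConfig-class] used to build the state.
#' @slot epoch integer epochs completed.
#' @slot lossHistory data.frame with one row per optimisation step.
#' @export
setClass("GanState", representation(
  gSR = "environment", gRS = "environment",
  dS = "environment", dR = "environment",
  optG = "environment", optD = "environment",
  buffers = "environment",
  config = "GanConfig", epoch = "integer", lossHistory = "data.frame"
))

setMethod("show", "GanState", function(object) {
  cat("GanState: mask-preserving CycleGAN\n",
    " generators: S(4ch) -> R(3ch) and R(3ch) -> S(4ch), base",
    object@config@baseChannels, "channels,",
    object@config@nResBlocks, "residual blocks\n",
    " epochs completed:", object@epoch, "|",
    nrow(object@lossHistory), "steps logged\n")
})

## ---- segmentation ----------------------------------------------------------

#' SegConfig: training configuration of the U-Net segmenter
#'
#' Defaults follow the study recipe: 45 epochs per phase, SGD with learning
#' rate 0.01, weight decay 0.001, momentum 0.95, and a step scheduler that
#' multiplies the rate by 0.1 every 5 epochs.
#'
#' @slot epochs training epochs per phase.
#' @slot learningRate,weightDecay,momentum SGD hyper-parameters.
#' @slot schedulerStep epochs between learning-rate reductions.
#' @slot schedulerGamma multiplicative reduction factor.
#' @slot binarizeThreshold probability threshold for predicted masks.
#' @slot batchSize images per SGD step (gradients averaged over the batch).
#' @slot gradClip global gradient-norm cap per step (Inf disables).
#' @slot hflipAugment logical; random horizontal flip during training.
#' @slot seed integer seed.
#' @export
setClass("SegConfig", representation(
  epochs = "integer", learningRate = "numeric", weightDecay = "numeric",
  momentum = "numeric", schedulerStep = "integer", schedulerGamma = "numeric",
  binarizeThreshold = "numeric", batchSize = "integer",
  gradClip = "numeric", hflipAugment = "logical", seed = "integer"
))

setValidity("SegConfig", function(object) {
  msgs <- character()
  if (object@epochs < 0L) msgs <- c(msgs, "epochs must be >= 0")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@binarizeThreshold <= 0 || object@binarizeThreshold >= 1)
    msgs <- c(msgs, "binarizeThreshold must be in (0, 1)")
  if (object@schedulerStep < 1L) msgs <- c(msgs, "schedulerStep must be >= 1")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@gradClip <= 0) msgs <- c(msgs, "gradClip must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SegConfig
#' @param epochs training epochs per phase.
#' @param learningRate,weightDecay,momentum SGD hyper-parameters.
#' @param schedulerStep,schedulerGamma step scheduler parameters.
#' @param binarizeThreshold mask probability threshold.
#' @param batchSize images per SGD step; the momentum-0.95 recipe assumes
#'   averaged mini-batch gradients (single-image steps amplify it into an
#'   effective 20x learning rate and can collapse training).
#' @param gradClip cap on the global gradient norm applied before each
#'   update; with momentum 0.95 a run of large gradients otherwise
#'   accumulates into weight steps that kill the network's features
#'   (constant-output collapse). Inf disables clipping.
#' @param hflipAugment random horizontal flip augmentation.
#' @param seed integer seed.
#' @return a [SegConfig-class] object.
#' @export
segConfig <- function(epochs = 45L, learningRate = 0.01, weightDecay = 0.001,
                      momentum = 0.95, schedulerStep = 5L,
                      schedulerGamma = 0.1, binarizeThreshold = 0.5,
                      batchSize = 4L, gradClip = 1, hflipAugment = FALSE,
                      seed = 1L) {
  new("SegConfig", epochs = as.integer(epochs),
      learningRate = as.numeric(learningRate),
      weightDecay = as.numeric(weightDecay), momentum = as.numeric(momentum),
      schedulerStep = as.integer(schedulerStep),
      schedulerGamma = as.numeric(schedulerGamma),
      binarizeThreshold = as.numeric(binarizeThreshold),
      batchSize = as.integer(batchSize), gradClip = as.numeric(gradClip),
      hflipAugment = isTRUE(hflipAugment), seed = as.integer(seed))
}

#' UNetSpec: architecture of the U-Net segmenter
#'
#' A standard encoder-decoder with skip connections stands in for the
#' study's customised variant: `depth` pooling stages, `baseChannels`
#' filters at the top level (doubled per stage), bilinear upsampling in the
#' decoder, and a sigmoid per-pixel probability output.
#'
#' @slot depth number of down/up stages (>= 2).
#' @slot baseChannels filters at the first stage.
#' @slot inChannels input channels (3 for RGB).
#' @slot outChannels output channels (1: foreground probability).
#' @export
setClass("UNetSpec", representation(
  depth = "integer", baseChannels = "integer",
  inChannels = "integer", outChannels = "integer",
  norm = "character"
))

setValidity("UNetSpec", function(object) {
  if (object@depth < 2L) return("depth must be >= 2")
  if (object@baseChannels < 1L) return("baseChannels must be >= 1")
  if (!object@norm %in% c("none", "instance"))
    return("norm must be 'none' or 'instance'")
  TRUE
})

#' Construct a UNetSpec
#' @param depth down/up stages.
#' @param baseChannels filters at the first stage.
#' @param inChannels,outChannels input/output channel counts.
#' @param norm "none" (default) gives the classic plain convolution blocks;
#'   "instance" inserts instance normalisation after every convolution.
#'   Note that instance normalisation makes the segmenter largely invariant
#'   to global colour shifts, which also blunts its sensitivity to
#'   appearance domain gaps — sometimes desirable, sometimes exactly what
#'   an experiment must not hide.
#' @return a [UNetSpec-class] object.
#' @export
unetSpec <- function(depth = 4L, baseChannels = 64L, inChannels = 3L,
                     outChannels = 1L, norm = c("none", "instance")) {
  new("UNetSpec", depth = as.integer(depth),
      baseChannels = as.integer(baseChannels),
      inChannels = as.integer(inChannels),
      outChannels = as.integer(outChannels), norm = match.arg(norm))
}

#' TrainHistory: per-epoch record of segmenter training
#'
#' @slot history data.frame with columns epoch, train_loss, val_dice, val_iou.
#' @slot bestEpoch 1-based index of the epoch with maximal validation Dice
#'   (0 when no epochs were run).
#' @export
setClass("TrainHistory", representation(history = "data.frame",
                                        bestEpoch = "integer"))

setValidity("TrainHistory", function(object) {
  h <- object@history
  need <- c("epoch", "train_loss", "val_dice", "val_iou")
  if (nrow(h) > 0 && !all(need %in% names(h)))
    return(paste("history needs columns", paste(need, collapse = ", ")))
  if (nrow(h) > 0) {
    if (object@bestEpoch < 1L || object@bestEpoch > nrow(h))
      return("bestEpoch out of range")
    if (h$val_dice[object@bestEpoch] < max(h$val_dice) - 1e-12)
      return("bestEpoch must maximise validation Dice")
  }
  TRUE
})

setMethod("show", "TrainHistory", function(object) {
  h <- object@history
  cat("TrainHistory:", nrow(h), "epochs")
  if (nrow(h) > 0)
    cat("; best epoch", object@bestEpoch,
        "(val Dice", round(h$val_dice[object@bestEpoch], 4), ")")
  cat("\n")
})

## ---- pseudo-labelling ------------------------------------------------------

#' PseudoCandidate: a pseudo-label candidate with its confidence score
#'
#' @slot imageRef path of the unlabelled source image.
#' @slot probabilityMap (H, W) matrix of foreground probabilities.
#' @slot predictedMask (H, W) integer matrix, the thresholded map.
#' @slot qualityScore confidence proxy in \[0, 1\].
#' @export
setClass("PseudoCandidate", representation(
  imageRef = "character", probabilityMap = "matrix",
  predictedMask = "matrix", qualityScore = "numeric"
))

setValidity("PseudoCandidate", function(object) {
  if (!identical(dim(object@probabilityMap), dim(object@predictedMask)))
    return("probability map and mask dimensions must match")
  if (!all(object@predictedMask %in% c(0L, 1L)))
    return("predicted mask must be binary")
  if (object@qualityScore < 0 || object@qualityScore > 1)
    return("qualityScore must lie in [0, 1]")
  TRUE
})

setMethod("show", "PseudoCandidate", function(object) {
  cat("PseudoCandidate", basename(object@imageRef), ": score",
      round(object@qualityScore, 4), ",",
      sum(object@predictedMask), "foreground px\n")
})

#' SelectionCriterion: how pseudo-label candidates are selected
#'
#' Exactly one mode is active: `top_k` (the k best scores),
#' `score_threshold` (all candidates at or above a threshold), or
#' `manual_review_list` (an explicit list of image refs, mirroring the
#' study's manual curation). Ties break lexicographically by image ref.
#'
#' @slot mode one of "top_k", "score_threshold", "manual_review_list".
#' @slot k number selected in top_k mode.
#' @slot threshold minimal score in score_threshold mode.
#' @slot reviewList image refs in manual_review_list mode.
#' @export
setClass("SelectionCriterion", representation(
  mode = "character", k = "integer", threshold = "numeric",
  reviewList = "character"
))

setValidity("SelectionCriterion", function(object) {
  if (!object@mode %in% c("top_k", "score_threshold", "manual_review_list"))
    return("mode must be top_k, score_threshold or manual_review_list")
  if (object@mode == "top_k" && object@k < 1L)
    return("top_k mode requires k >= 1")
  TRUE
})

#' Construct a SelectionCriterion
#' @param mode selection mode.
#' @param k number to keep (top_k mode; study value 99 of 360).
#' @param threshold minimal score (score_threshold mode).
#' @param reviewList image refs (manual_review_list mode).
#' @return a [SelectionCriterion-class] object.
#' @export
selectionCriterion <- function(mode = c("top_k", "score_threshold",
                                        "manual_review_list"),
                               k = 99L, threshold = 0.9,
                               reviewList = character()) {
  mode <- match.arg(mode)
  new("SelectionCriterion", mode = mode, k = as.integer(k),
      threshold = as.numeric(threshold), reviewList = as.character(reviewList))
}

## ---- metrics ---------------------------------------------------------------

#' MetricsReport: per-(model, dataset) segmentation scores
#'
#' @slot modelId,datasetId identifiers.
#' @slot meanDice,meanIoU unweighted per-image means in \[0, 1\].
#' @slot nImages number of evaluated images.
#' @slot perImage data.frame with columns dice, iou (may be empty when the
#'   report was built from published summary values).
#' @export
setClass("MetricsReport", representation(
  modelId = "character", datasetId = "character",
  meanDice = "numeric", meanIoU = "numeric",
  nImages = "integer", perImage = "data.frame"
))

setValidity("MetricsReport", function(object) {
  if (object@meanDice < 0 || object@meanDice > 1 ||
      object@meanIoU < 0 || object@meanIoU > 1)
    return("mean scores must lie in [0, 1]")
  if (nrow(object@perImage) > 0) {
    if (!all(c("dice", "iou") %in% names(object@perImage)))
      return("perImage needs columns dice, iou")
    if (abs(mean(object@perImage$dice) - object@meanDice) > 1e-9 ||
        abs(mean(object@perImage$iou) - object@meanIoU) > 1e-9)
      return("means must equal the arithmetic mean of perImage entries")
  }
  TRUE
})

#' Construct a MetricsReport
#'
#' Either from per-image scores (means are derived) or from summary values
#' (e.g. a published table), in which case `perImage` stays empty.
#'
#' @param modelId,datasetId identifiers.
#' @param meanDice,meanIoU summary scores (ignored when perImage is given).
#' @param nImages evaluated image count.
#' @param perImage optional data.frame with columns dice, iou.
#' @return a [MetricsReport-class] object.
#' @export
metricsReport <- function(modelId, datasetId, meanDice = NA_real_,
                          meanIoU = NA_real_, nImages = 0L,
                          perImage = data.frame()) {
  if (nrow(perImage) > 0) {
    meanDice <- mean(perImage$dice)
    meanIoU <- mean(perImage$iou)
    nImages <- nrow(perImage)
  }
  new("MetricsReport", modelId = as.character(modelId),
      datasetId = as.character(datasetId), meanDice = as.numeric(meanDice),
      meanIoU = as.numeric(meanIoU), nImages = as.integer(nImages),
      perImage = perImage)
}

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport [", object@modelId, "on", object@datasetId, "]: Dice",
      round(object@meanDice, 3), "IoU", round(object@meanIoU, 3),
      "over", object@nImages, "images\n")
})
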