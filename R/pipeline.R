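## End-to-end orchestration of the three-phase training study:
##   A: U-Net trained on raw cut-and-paste composites (delta-S),
##   B: U-Net trained on GAN-translated composites (delta-GAN),
##   C: B fine-tuned on delta-GAN plus selected pseudo-labels (delta-PL),
## all evaluated on held-out annotated real-domain frames.

#' Bundle pipeline configurations at a named scale
#'
#' `"study"` mirrors the full protocol: 256 px frames, 11,000 composites
#' (10,000/1,000 split), 60 GAN epochs, 45 segmenter epochs per phase, a
#' depth-4/base-64 U-Net and 99 pseudo-labels — sizes that call for long
#' compute. `"demo"` is the package's reduced demonstration scale used by
#' its tests and reproduction script: 64 px frames, 200 composites, a
#' base-8 GAN with 2 residual blocks trained 3 epochs on 60 source samples,
#' a depth-3/base-8 U-Net trained 3 epochs per phase, and 11 of 40 frames
#' pseudo-labelled — the same phases at a size a single CPU handles in
#' minutes.
#'
#' @param scale "study" or "demo".
#' @param seed integer master seed propagated to every stage.
#' @return named list: fixtures, synthesis, gan, seg, unet, pseudo,
#'   nGanSourceSamples, minArea.
#' @export
pipelineConfigs <- function(scale = c("study", "demo"), seed = 1L) {
  scale <- match.arg(scale)
  seed <- as.integer(seed)
  if (scale == "study") {
    list(
      fixtures = fixtureConfig(seed = seed),
      synthesis = synthesisConfig(seed = seed),
      gan = ganConfig(seed = seed),
      seg = segConfig(seed = seed),
      unet = unetSpec(),
      pseudo = selectionCriterion("top_k", k = 99L),
      nGanSourceSamples = NA_integer_,
      minArea = 10L)
  } else {
    list(
      fixtures = fixtureConfig(seed = seed, imageHeight = 64L,
                               imageWidth = 64L, blobsPerFrame = c(4L, 9L),
                               blobAxes = c(4, 10), nBackgroundFrames = 12L,
                               nRealFrames = 40L, nTestFrames = 12L),
      synthesis = synthesisConfig(nImages = 200L, headsPerImage = c(4L, 10L),
                                  scaleRange = c(0.8, 1.25),
                                  trainFraction = 0.9, seed = seed),
      gan = ganConfig(epochs = 3L, cropSize = 64L, baseChannels = 8L,
                      nResBlocks = 2L, seed = seed),
      seg = segConfig(epochs = 3L, seed = seed),
      unet = unetSpec(depth = 3L, baseChannels = 8L),
      pseudo = selectionCriterion("top_k", k = 11L),
      nGanSourceSamples = 60L,
      minArea = 8L)
  }
}

## rebuild a U-Net and copy the parameter values over, so fine-tuning a
## clone leaves the original untouched
cloneUnet <- function(model) {
  m2 <- nnUNet(model$spec)
  paramsRestore(nnParams(m2), paramsSnapshot(nnParams(model)))
  m2
}

#' Run the full annotation-preserving synthesis and segmentation pipeline
#'
#' Generates a fixture corpus, synthesises the cut-and-paste dataset,
#' trains the mask-preserving CycleGAN and translates the dataset, trains
#' segmenters A (raw composites) and B (translated composites), optionally
#' pseudo-labels the unlabelled real pool and fine-tunes B into C, and
#' evaluates every model on the held-out annotated test frames.
#'
#' @param configs configuration bundle from [pipelineConfigs()].
#' @param workDir writable working directory for all intermediate datasets.
#' @param withPseudoLabel run the pseudo-label fine-tuning phase.
#' @param verbose print phase banners.
#' @return list with `reports` (MetricsReport per model), `deltas`
#'   (A vs B percentage points), `ratios` (C vs A IoU ratios when C was
#'   trained), `manifests`, `histories`, `models`, and `ganState`.
#' @export
runWheatPipeline <- function(configs, workDir, withPseudoLabel = TRUE,
                             verbose = TRUE) {
  say <- function(...) if (verbose) message("[maskcycle] ", ...)
  dir.create(workDir, showWarnings = FALSE, recursive = TRUE)

  say("generating fixture corpus")
  corpus <- generateFixtureCorpus(configs$fixtures, file.path(workDir, "fix"))

  say("extracting cutouts and synthesising composites")
  src <- annotatedSample(readImagePNG(corpus$source$image_path[1]),
                         readMaskPNG(corpus$source$mask_path[1]))
  cuts <- extractCutouts(src, minArea = configs$minArea)
  mS <- synthesizeDataset(configs$synthesis, cuts, corpus$backgrounds,
                          file.path(workDir, "delta_s"))
  trainS <- mS[mS$split == "train", ]
  valS <- mS[mS$split == "val", ]

  say("training the mask-preserving CycleGAN")
  nGan <- configs$nGanSourceSamples
  ganTrainS <- if (is.na(nGan) || nGan >= nrow(trainS)) trainS
               else trainS[seq_len(nGan), ]
  ganState <- trainGan(configs$gan, ganTrainS, corpus$real)

  say("translating the composite dataset")
  mG <- buildGanDataset(ganState, mS, file.path(workDir, "delta_gan"))
  trainG <- mG[mG$split == "train", ]
  valG <- mG[mG$split == "val", ]

  say("training segmenter A on the raw composites")
  A <- trainSegmenter(configs$seg, configs$unet, trainS, valS)
  say("training segmenter B on the translated composites")
  B <- trainSegmenter(configs$seg, configs$unet, trainG, valG)

  thr <- configs$seg@binarizeThreshold
  reports <- list(
    A = evaluateModel(A$model, corpus$test, thr, "A", "fixture_test"),
    B = evaluateModel(B$model, corpus$test, thr, "B", "fixture_test"))
  models <- list(A = A$model, B = B$model)
  histories <- list(A = A$history, B = B$history)
  manifests <- list(corpus = corpus, deltaS = mS, deltaGAN = mG)

  if (withPseudoLabel) {
    say("pseudo-labelling the unlabelled real pool")
    cands <- generateCandidates(B$model, corpus$real, thr)
    mPL <- selectCandidates(cands, configs$pseudo,
                            file.path(workDir, "delta_pl"))
    say("fine-tuning into model C")
    C <- fineTune(cloneUnet(B$model), configs$seg, list(trainG, mPL), valG)
    reports$C <- evaluateModel(C$model, corpus$test, thr, "C", "fixture_test")
    models$C <- C$model
    histories$C <- C$history
    manifests$deltaPL <- mPL
  }

  out <- list(reports = reports,
              deltas = deltaTable(list(reports$A), list(reports$B)),
              manifests = manifests, histories = histories,
              models = models, ganState = ganState)
  if (withPseudoLabel)
    out$ratios <- ratioTable(list(reports$A), list(reports$C))
  out
}
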