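## U-Net segmenter, trained with the study recipe: binary cross-entropy,
## SGD (lr 0.01, weight decay 0.001, momentum 0.95), step scheduler (x0.1
## every 5 epochs), best model chosen by validation Dice.

#' Build a U-Net segmentation model
#'
#' Encoder-decoder with skip connections; the output is a per-pixel
#' foreground probability map with the input's spatial dimensions. Input
#' dimensions must be divisible by 2^depth.
#'
#' @param spec a [UNetSpec-class].
#' @param seed integer seed for parameter initialisation.
#' @return a model environment.
#' @export
buildUnet <- function(spec, seed = 1L) {
  validObject(spec)
  set.seed(seed)
  nnUNet(spec)
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of -\[m log p + (1 - m) log(1 - p)\], with probabilities
#' clipped to \[eps, 1 - eps\] for stability.
#'
#' @param probabilities matrix/array of probabilities in \[0, 1\].
#' @param mask binary matrix/array of the same dimensions.
#' @param eps clipping epsilon.
#' @return non-negative scalar.
#' @export
bceLoss <- function(probabilities, mask, eps = 1e-7) {
  if (!identical(dim(probabilities), dim(mask)) &&
      !identical(length(probabilities), length(mask)))
    stop("probability map and mask dimensions must match")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  m <- as.numeric(mask)
  -mean(m * log(p) + (1 - m) * log(1 - p))
}

## gradient of bceLoss w.r.t. the (clipped) probabilities
.bceGrad <- function(probabilities, mask, eps = 1e-7) {
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  m <- as.numeric(mask)
  arr <- (p - m) / (p * (1 - p)) / length(p)
  array(arr, dim(probabilities))
}

#' Step-scheduler learning rate
#'
#' lr(e) = learningRate * gamma^floor(e / step) with 0-based epoch index e;
#' with the defaults, epochs 0-4 train at 0.01, epochs 5-9 at 0.001, and so
#' on.
#'
#' @param config a [SegConfig-class].
#' @param epoch 0-based epoch index (vectorised).
#' @return learning rate(s).
#' @export
schedulerLR <- function(config, epoch) {
  config@learningRate * config@schedulerGamma^(epoch %/% config@schedulerStep)
}

#' Predict a binary mask for one image
#'
#' Thresholds the model's probability map; pixels with p exactly equal to
#' the threshold count as foreground.
#'
#' @param model a U-Net model environment.
#' @param image (H, W, 3) array in \[0, 1\].
#' @param threshold probability threshold in (0, 1).
#' @return list with `mask` (integer matrix in {0, 1}) and `probabilities`
#'   (numeric matrix).
#' @export
predictMask <- function(model, image, threshold = 0.5) {
  pm <- netForward(model, image, train = FALSE)
  prob <- matrix(pm, dim(pm)[1], dim(pm)[2])
  list(mask = binarizeProbabilities(prob, threshold), probabilities = prob)
}

#' Threshold a probability map into a binary mask
#'
#' Pixels with probability greater than or equal to the threshold become
#' foreground (ties count as foreground).
#'
#' @param probabilities numeric matrix in \[0, 1\].
#' @param threshold probability threshold in (0, 1).
#' @return integer matrix in {0, 1}.
#' @export
binarizeProbabilities <- function(probabilities, threshold = 0.5) {
  matrix(as.integer(probabilities >= threshold),
         nrow(probabilities), ncol(probabilities))
}

.loadPair <- function(row) {
  list(image = readImagePNG(row$image_path), mask = readMaskPNG(row$mask_path))
}

.valScores <- function(model, pairs, threshold) {
  d <- numeric(length(pairs)); j <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    pr <- predictMask(model, pairs[[i]]$image, threshold)
    d[i] <- dice(pr$mask, pairs[[i]]$mask)
    j[i] <- iou(pr$mask, pairs[[i]]$mask)
  }
  c(dice = mean(d), iou = mean(j))
}

#' Train the U-Net segmenter
#'
#' Runs `config@epochs` epochs of mini-batch SGD over the train manifest
#' (shuffled each epoch, gradients averaged over `batchSize` images,
#' optional random horizontal flip), evaluates mean
#' Dice/IoU on the validation manifest after every epoch, and returns the
#' parameters of the best-validation-Dice epoch together with the training
#' history.
#'
#' @param config a [SegConfig-class].
#' @param spec a [UNetSpec-class] (ignored when `initModel` is given).
#' @param train,val manifests with masks on every row.
#' @param initModel optional model environment to continue from
#'   (fine-tuning); its parameters are updated in place.
#' @param outDir optional checkpoint directory (`seg_{phase}_{epoch}.ckpt`).
#' @param phase label used in checkpoint names and messages.
#' @return list with `model` (best-epoch parameters) and
#'   `history` (a [TrainHistory-class]).
#' @export
trainSegmenter <- function(config, spec, train, val, initModel = NULL,
                           outDir = NULL, phase = "train") {
  validObject(config)
  validateManifest(train, requireMasks = TRUE)
  validateManifest(val, requireMasks = TRUE)
  if (nrow(train) == 0L || nrow(val) == 0L)
    stop("train and val manifests must be non-empty")
  model <- if (is.null(initModel)) buildUnet(spec, config@seed) else initModel
  params <- nnParams(model)
  if (config@epochs == 0L) {
    hist <- new("TrainHistory",
                history = data.frame(epoch = integer(), train_loss = numeric(),
                                     val_dice = numeric(), val_iou = numeric()),
                bestEpoch = 0L)
    return(list(model = model, history = hist))
  }
  set.seed(config@seed + 1L)                   # training-loop randomness
  opt <- optSGD(params, config@learningRate, config@momentum,
                config@weightDecay)
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  trainPairs <- lapply(seq_len(nrow(train)), function(i) .loadPair(train[i, ]))
  valPairs <- lapply(seq_len(nrow(val)), function(i) .loadPair(val[i, ]))
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_dice = numeric(), val_iou = numeric())
  best <- list(dice = -Inf, snap = NULL, epoch = 0L)
  for (e in seq_len(config@epochs)) {
    opt$lr <- schedulerLR(config, e - 1L)
    ord <- sample(length(trainPairs))
    lossSum <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
    for (batch in batches) {
      zeroGrads(params)
      for (i in batch) {
        img <- trainPairs[[i]]$image
        msk <- trainPairs[[i]]$mask
        if (config@hflipAugment && runif(1) < 0.5) {
          img <- img[, ncol(msk):1, , drop = FALSE]
          msk <- msk[, ncol(msk):1, drop = FALSE]
        }
        pm <- netForward(model, img, train = TRUE)
        target <- array(msk, dim(pm))
        lossSum <- lossSum + bceLoss(pm, target)
        netBackward(model, .bceGrad(pm, target))
      }
      if (length(batch) > 1L)                  # mean gradient over the batch
        for (p in params) p$env[[p$g]] <- p$env[[p$g]] / length(batch)
      clipGradNorm(params, config@gradClip)
      optStep(opt)
    }
    vs <- .valScores(model, valPairs, config@binarizeThreshold)
    hist[nrow(hist) + 1L, ] <- list(e, lossSum / length(ord),
                                    vs["dice"], vs["iou"])
    if (vs["dice"] > best$dice) {
      best$dice <- vs["dice"]
      best$snap <- paramsSnapshot(params)
      best$epoch <- e
    }
    if (!is.null(outDir))
      saveRDS(paramsSnapshot(params),
              file.path(outDir, sprintf("seg_%s_%d.ckpt", phase, e)))
  }
  paramsRestore(params, best$snap)
  list(model = model,
       history = new("TrainHistory", history = hist,
                     bestEpoch = as.integer(best$epoch)))
}

#' Fine-tune a trained segmenter on pooled manifests
#'
#' Concatenates the given manifests into one training pool and continues
#' training from the model's current parameters with the same recipe
#' (fresh optimizer state and schedule).
#'
#' @param model a trained model environment (updated in place).
#' @param config a [SegConfig-class].
#' @param manifests list of manifests with masks; pooled row-wise.
#' @param val validation manifest.
#' @param outDir optional checkpoint directory.
#' @return list with `model` and `history`, as [trainSegmenter()].
#' @export
fineTune <- function(model, config, manifests, val, outDir = NULL) {
  stopifnot(is.list(manifests), length(manifests) >= 1L)
  pooled <- do.call(rbind, manifests)
  trainSegmenter(config, spec = NULL, train = pooled, val = val,
                 initModel = model, outDir = outDir, phase = "finetune")
}
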