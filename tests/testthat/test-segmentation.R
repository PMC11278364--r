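tinySpec <- function() unetSpec(depth = 2L, baseChannels = 4L)

## one tiny labelled frame written to disk as a manifest row
tinySegData <- function(seed = 1L, size = 32L, dir = tempfile("seg")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fr <- makeAnnotatedFrame(testFixtureConfig(seed = seed, size = size))
  ip <- file.path(dir, "i.png"); mp <- file.path(dir, "m.png")
  writeImagePNG(sampleImage(fr), ip)
  writeMaskPNG(sampleMask(fr), mp)
  list(frame = fr, manifest = newManifest(ip, mp))
}

test_that("binary cross-entropy matches enumeration and its closed forms", {
  ## p = 0.5 everywhere -> ln 2 regardless of the mask
  anyMask <- matrix(c(0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L), 3, 3)
  expect_equal(bceLoss(matrix(0.5, 3, 3), anyMask), log(2), tolerance = 1e-9)
  ## p = m (post-clipping) -> ~0
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(bceLoss(m, m), 1e-5)
  ## 2x2 hand sum
  p <- matrix(c(0.9, 0.1, 0.8, 0.3), 2, 2)
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  hand <- -(log(0.9) + log(1 - 0.1) + log(0.8) + log(1 - 0.3)) / 4
  expect_equal(bceLoss(p, m), hand, tolerance = 1e-9)
  ## random 4x4 elementwise enumeration
  set.seed(23)
  p <- matrix(runif(16, 0.05, 0.95), 4, 4)
  m <- matrix(as.integer(runif(16) < 0.5), 4, 4)
  hand <- 0
  for (i in 1:4) for (j in 1:4)
    hand <- hand - (m[i, j] * log(p[i, j]) +
                    (1 - m[i, j]) * log(1 - p[i, j]))
  expect_equal(bceLoss(p, m), hand / 16, tolerance = 1e-9)
  expect_error(bceLoss(matrix(0.5, 2, 2), matrix(0L, 3, 3)), "match")
})

test_that("the step scheduler follows lr * gamma^floor(e/step) exactly", {
  cfg <- segConfig()
  expect_identical(schedulerLR(cfg, 0:14), 0.01 * 0.1^(0:14 %/% 5))
  ## after epoch 5 (0-based index 5) the rate is 0.001
  expect_equal(schedulerLR(cfg, 5L), 0.001)
  cfg2 <- segConfig(learningRate = 0.2, schedulerStep = 3L,
                    schedulerGamma = 0.5)
  expect_equal(schedulerLR(cfg2, 0:8), 0.2 * 0.5^(0:8 %/% 3))
})

test_that("the U-Net preserves dims, emits probabilities, rejects bad dims", {
  model <- buildUnet(unetSpec(depth = 4L, baseChannels = 2L), seed = 3L)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  mc <- asNamespace("maskcycle")
  y <- mc$netForward(model, x, train = FALSE)
  expect_equal(dim(y), c(64L, 64L, 1L))
  expect_true(all(y >= 0 & y <= 1))
  expect_error(mc$netForward(model, array(0.5, c(40, 40, 3)), FALSE),
               "divisible")
})

test_that("same seed gives identical initial parameters", {
  mc <- asNamespace("maskcycle")
  m1 <- buildUnet(tinySpec(), seed = 8L)
  m2 <- buildUnet(tinySpec(), seed = 8L)
  m3 <- buildUnet(tinySpec(), seed = 9L)
  expect_identical(mc$paramsSnapshot(mc$nnParams(m1)),
                   mc$paramsSnapshot(mc$nnParams(m2)))
  expect_false(identical(mc$paramsSnapshot(mc$nnParams(m1)),
                         mc$paramsSnapshot(mc$nnParams(m3))))
})

test_that("probability binarization thresholds with ties to foreground", {
  expect_equal(binarizeProbabilities(matrix(0.7, 2, 2), 0.5),
               matrix(1L, 2, 2))
  expect_equal(binarizeProbabilities(matrix(0.3, 2, 2), 0.5),
               matrix(0L, 2, 2))
  expect_equal(binarizeProbabilities(matrix(0.5, 2, 2), 0.5),
               matrix(1L, 2, 2))   # exact tie -> foreground
  ## monotone: raising the threshold never adds foreground pixels
  set.seed(4)
  pm <- matrix(runif(100), 10, 10)
  prev <- binarizeProbabilities(pm, 0.1)
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- binarizeProbabilities(pm, th)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("zero-epoch training returns the untouched model, empty history", {
  mc <- asNamespace("maskcycle")
  dat <- tinySegData(seed = 2L)
  cfg <- segConfig(epochs = 0L, seed = 5L)
  res <- trainSegmenter(cfg, tinySpec(), dat$manifest, dat$manifest)
  expect_equal(nrow(res$history@history), 0)
  expect_equal(res$history@bestEpoch, 0L)
  ref <- buildUnet(tinySpec(), seed = 5L)
  expect_identical(mc$paramsSnapshot(mc$nnParams(res$model)),
                   mc$paramsSnapshot(mc$nnParams(ref)))
})

test_that("training returns the argmax-validation-Dice parameters", {
  dat <- tinySegData(seed = 6L)
  cfg <- segConfig(epochs = 3L, seed = 7L)
  res <- trainSegmenter(cfg, tinySpec(), dat$manifest, dat$manifest)
  h <- res$history@history
  expect_equal(nrow(h), 3)
  expect_equal(res$history@bestEpoch, which.max(h$val_dice))
  ## the returned model reproduces the best epoch's validation Dice
  ## (evaluate on the same on-disk 8-bit image the trainer validated on)
  img <- readImagePNG(dat$manifest$image_path[1])
  msk <- readMaskPNG(dat$manifest$mask_path[1])
  pr <- predictMask(res$model, img)
  expect_equal(dice(pr$mask, msk), max(h$val_dice), tolerance = 1e-12)
})

test_that("fine-tuning pools manifests; zero epochs keep parameters", {
  mc <- asNamespace("maskcycle")
  dat <- tinySegData(seed = 9L)
  model <- buildUnet(tinySpec(), seed = 1L)
  before <- mc$paramsSnapshot(mc$nnParams(model))
  res <- fineTune(model, segConfig(epochs = 0L),
                  list(dat$manifest, dat$manifest), dat$manifest)
  expect_identical(mc$paramsSnapshot(mc$nnParams(res$model)), before)
  pooled <- do.call(rbind, list(dat$manifest, dat$manifest))
  expect_equal(nrow(pooled), 2)
  ## one fine-tuning epoch changes parameters but keeps the contract
  res2 <- fineTune(model, segConfig(epochs = 1L, seed = 2L),
                   list(dat$manifest), dat$manifest)
  expect_equal(nrow(res2$history@history), 1)
})

test_that("manifest rows without masks are rejected for training", {
  dat <- tinySegData(seed = 3L)
  bad <- dat$manifest; bad$mask_path <- ""
  expect_error(trainSegmenter(segConfig(epochs = 1L), tinySpec(),
                              bad, dat$manifest), "mask")
})
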