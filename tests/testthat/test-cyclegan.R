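tinyGanConfig <- function(seed = 1L, epochs = 1L)
  ganConfig(epochs = epochs, cropSize = 32L, baseChannels = 4L,
            nResBlocks = 1L, seed = seed)

test_that("cycle losses match elementwise enumeration on small grids", {
  set.seed(17)
  a <- array(runif(4 * 4 * 4, -1, 1), c(4, 4, 4))
  b <- array(runif(4 * 4 * 4, -1, 1), c(4, 4, 4))
  hand <- 0
  for (i in 1:4) for (j in 1:4) for (c in 1:4)
    hand <- hand + abs(a[i, j, c] - b[i, j, c])
  expect_equal(cycleLossS(a, b), hand / 64, tolerance = 1e-12)
  expect_equal(cycleLossS(a, a), 0)
  expect_equal(cycleLossS(a, pmin(a + 0.25, 1)),
               mean(pmin(a + 0.25, 1) - a), tolerance = 1e-12)
  a3 <- a[, , 1:3]; b3 <- b[, , 1:3]
  hand3 <- sum(abs(a3 - b3)) / length(a3)
  expect_equal(cycleLossR(a3, b3), hand3, tolerance = 1e-12)
  expect_error(cycleLossS(a, b[1:3, , ]), "mismatch")
  expect_error(cycleLossR(a, a), "3 channels")
})

test_that("least-squares adversarial loss matches scalar enumeration", {
  expect_equal(adversarialLoss(matrix(1, 3, 3), TRUE), 0)
  expect_equal(adversarialLoss(matrix(0, 3, 3), TRUE), 1)
  m <- matrix(c(0.2, -0.1, 0.7, 1.3), 2, 2)
  handReal <- ((0.2 - 1)^2 + (-0.1 - 1)^2 + (0.7 - 1)^2 + (1.3 - 1)^2) / 4
  handFake <- (0.2^2 + 0.1^2 + 0.7^2 + 1.3^2) / 4
  expect_equal(adversarialLoss(m, TRUE), handReal, tolerance = 1e-12)
  expect_equal(adversarialLoss(m, FALSE), handFake, tolerance = 1e-12)
  expect_error(adversarialLoss(matrix(NaN, 2, 2), TRUE), "finite")
})

test_that("domain samples encode images and masks on the [-1, 1] scale", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  msk <- matrix(as.integer(runif(64) < 0.3), 8, 8)
  s <- domainSampleS(img, msk)
  expect_equal(dim(s@channels), c(8L, 8L, 4L))
  expect_true(all(s@channels[, , 4] %in% c(-1, 1)))
  expect_equal(sum(s@channels[, , 4] == 1), sum(msk))
  expect_equal(domainImage(s), img, tolerance = 1e-12)
  r <- domainSampleR(img)
  expect_equal(dim(r@channels), c(8L, 8L, 3L))
  expect_equal(domainImage(r), img, tolerance = 1e-12)
})

test_that("generators conserve channel arity through the double cycle", {
  st <- buildGan(tinyGanConfig(seed = 3L))
  pair <- makeTinyPairs(1, seed = 5L)[[1]]
  tr <- translateSample(st, pair$S)
  expect_equal(dim(tr@channels), c(32L, 32L, 3L))
  expect_true(all(abs(tr@channels) <= 1))
  rec <- recreateS(st, tr)
  expect_equal(dim(rec@channels), c(32L, 32L, 4L))
  backR <- translateSample(st, rec)
  expect_equal(dim(backR@channels), c(32L, 32L, 3L))
  expect_error(translateSample(st, pair$R), "4-channel")
  expect_error(recreateS(st, pair$S), "3-channel")
})

test_that("inference is deterministic and mask binarization sends ties up", {
  st <- buildGan(tinyGanConfig(seed = 3L))
  pair <- makeTinyPairs(1, seed = 5L)[[1]]
  t1 <- translateSample(st, pair$S)
  t2 <- translateSample(st, pair$S)
  expect_identical(t1@channels, t2@channels)
  rec <- recreateS(st, t1, binarizeMask = TRUE)
  expect_true(all(rec@channels[, , 4] %in% c(-1, 1)))
  ## the documented tie rule: values exactly 0 map to foreground (+1)
  mc <- asNamespace("maskcycle")
  arr <- array(0, c(2, 2, 4)); arr[, , 4] <- c(0, 0.7, -0.3, 0)
  binz <- ifelse(arr[, , 4] >= 0, 1, -1)
  expect_equal(binz, matrix(c(1, 1, -1, 1), 2, 2))
})

test_that("one training step yields finite losses and seeded reruns match", {
  pairs <- makeTinyPairs(2, seed = 9L)
  runSteps <- function() {
    st <- buildGan(tinyGanConfig(seed = 11L))
    set.seed(99)
    for (k in 1:3)
      st <- trainingStep(st, pairs[[(k - 1) %% 2 + 1]]$S,
                         pairs[[(k - 1) %% 2 + 1]]$R)$state
    st@lossHistory
  }
  h1 <- runSteps()
  expect_equal(nrow(h1), 3)
  expect_true(all(is.finite(as.matrix(h1))))
  expect_true(all(as.matrix(h1[, -1]) >= 0))
  h2 <- runSteps()
  expect_identical(h1, h2)
})

test_that("a zero learning rate leaves parameters unchanged", {
  mc <- asNamespace("maskcycle")
  st <- buildGan(tinyGanConfig(seed = 2L))
  st@optG$lr <- 0; st@optD$lr <- 0
  allParams <- c(st@optG$params, st@optD$params)
  before <- mc$paramsSnapshot(allParams)
  pair <- makeTinyPairs(1, seed = 6L)[[1]]
  invisible(trainingStep(st, pair$S, pair$R))
  expect_identical(mc$paramsSnapshot(allParams), before)
})

test_that("channel-arity violations in batches are rejected", {
  st <- buildGan(tinyGanConfig(seed = 2L))
  pair <- makeTinyPairs(1, seed = 6L)[[1]]
  expect_error(trainingStep(st, list(pair$R@channels), list(pair$R)),
               "arity")
  expect_error(trainingStep(st, list(), list(pair$R)), "non-empty")
})

test_that("zero-epoch training returns the freshly initialised state", {
  mc <- asNamespace("maskcycle")
  corp <- generateFixtureCorpus(testFixtureConfig(seed = 14L, size = 32L),
                                withr::local_tempdir())
  cfg <- tinyGanConfig(seed = 7L, epochs = 0L)
  st <- trainGan(cfg, corp$source, corp$real)
  ref <- buildGan(cfg)
  expect_identical(mc$paramsSnapshot(c(st@optG$params, st@optD$params)),
                   mc$paramsSnapshot(c(ref@optG$params, ref@optD$params)))
  expect_equal(st@epoch, 0L)
  expect_equal(nrow(st@lossHistory), 0)
})

test_that("training writes one checkpoint per epoch", {
  corp <- generateFixtureCorpus(
    testFixtureConfig(seed = 15L, size = 32L, nRealFrames = 2L),
    withr::local_tempdir())
  out <- withr::local_tempdir()
  st <- trainGan(tinyGanConfig(seed = 5L, epochs = 2L),
                 corp$source[1, ], corp$real, outDir = out)
  expect_equal(st@epoch, 2L)
  expect_setequal(list.files(out, pattern = "ckpt$"),
                  c("gan_epoch1.ckpt", "gan_epoch2.ckpt"))
  reloaded <- readRDS(file.path(out, "gan_epoch2.ckpt"))
  pair <- makeTinyPairs(1, seed = 6L)[[1]]
  expect_identical(translateSample(reloaded, pair$S)@channels,
                   translateSample(st, pair$S)@channels)
})

test_that("a source manifest row without a mask is rejected", {
  corp <- generateFixtureCorpus(testFixtureConfig(seed = 16L, size = 32L),
                                withr::local_tempdir())
  bad <- corp$source
  bad$mask_path <- ""
  expect_error(trainGan(tinyGanConfig(), bad, corp$real), "mask")
})

test_that("dataset translation copies masks byte-for-byte and keeps splits", {
  corp <- generateFixtureCorpus(testFixtureConfig(seed = 18L, size = 32L),
                                withr::local_tempdir(), nSourceFrames = 3L)
  manifest <- corp$source
  manifest$split <- c("train", "val", "train")
  st <- buildGan(tinyGanConfig(seed = 4L))
  out <- withr::local_tempdir()
  mG <- buildGanDataset(st, manifest, out)
  expect_equal(nrow(mG), nrow(manifest))
  expect_identical(mG$split, manifest$split)
  for (i in seq_len(nrow(mG)))
    expect_identical(unname(tools::md5sum(mG$mask_path[i])),
                     unname(tools::md5sum(manifest$mask_path[i])))
  ## translated images decode to the generator's output
  s1 <- domainSampleS(readImagePNG(manifest$image_path[1]),
                      readMaskPNG(manifest$mask_path[1]))
  tr <- domainImage(translateSample(st, s1))
  reread <- readImagePNG(mG$image_path[1])
  expect_lt(max(abs(reread - tr)), 1 / 255)   # 8-bit quantisation only
})
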