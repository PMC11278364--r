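test_that("cutout extraction matches a flood-fill component oracle", {
  ## single solid square
  m <- matrix(0L, 12, 12); m[4:8, 5:9] <- 1L
  s <- annotatedSample(array(0.5, c(12, 12, 3)), m)
  cuts <- extractCutouts(s, minArea = 1L)
  expect_length(cuts, 1)
  expect_equal(sum(cuts[[1]]@alpha), 25)
  expect_equal(dim(cuts[[1]]@alpha), c(5L, 5L))

  ## diagonal-only touch: one component under 8-connectivity, two under 4
  m <- matrix(0L, 6, 6); m[2, 2] <- 1L; m[3, 3] <- 1L
  s <- annotatedSample(array(0.5, c(6, 6, 3)), m)
  expect_equal(oracleComponentCount(m, 8), 1)
  expect_equal(oracleComponentCount(m, 4), 2)
  expect_length(extractCutouts(s, minArea = 1L), 1)

  ## random masks: component count and total area agree with the oracle
  set.seed(41)
  for (rep in 1:5) {
    m <- matrix(as.integer(runif(20 * 20) < 0.25), 20, 20)
    s <- annotatedSample(array(0.5, c(20, 20, 3)), m)
    cuts <- extractCutouts(s, minArea = 1L)
    expect_length(cuts, oracleComponentCount(m, 8))
    expect_equal(sum(vapply(cuts, function(c) sum(c@alpha), numeric(1))),
                 sum(m))
  }
})

test_that("empty masks yield no cutouts and minArea filters small ones", {
  s <- annotatedSample(array(0.5, c(8, 8, 3)), matrix(0L, 8, 8))
  expect_length(extractCutouts(s), 0)
  m <- matrix(0L, 8, 8); m[2, 2] <- 1L; m[5:7, 5:7] <- 1L
  s <- annotatedSample(array(0.5, c(8, 8, 3)), m)
  expect_length(extractCutouts(s, minArea = 2L), 1)
})

test_that("invalid annotated samples are rejected at construction", {
  expect_error(annotatedSample(array(0.5, c(8, 8, 3)),
                               matrix(2L, 8, 8)), "binary")
  expect_error(annotatedSample(array(0.5, c(8, 8, 3)),
                               matrix(0L, 6, 8)), "dimensions")
})

test_that("instance sampling honours counts, point ranges and seeds", {
  cfg <- synthesisConfig(nImages = 5L, headsPerImage = c(3L, 3L),
                         scaleRange = c(1, 1), rotationRange = c(0, 0),
                         seed = 4L)
  inst <- sampleInstances(cfg, nCutouts = 4L, dims = c(32L, 32L))
  expect_equal(nrow(inst), 3)
  expect_true(all(inst$scale == 1) && all(inst$rotation == 0))
  expect_true(all(inst$cutoutIndex %in% 1:4))
  expect_true(all(inst$centerRow >= 0 & inst$centerRow <= 31))
  expect_identical(inst, sampleInstances(cfg, 4L, c(32L, 32L)))
  expect_warning(empty <- sampleInstances(cfg, 0L, c(32L, 32L)), "no cutouts")
  expect_equal(nrow(empty), 0)
})

test_that("zero instances leave the background and mask untouched", {
  bg <- array(runif(24 * 24 * 3), c(24, 24, 3))
  cfg <- synthesisConfig(nImages = 1L, headsPerImage = c(3L, 3L), seed = 1L)
  out <- renderPaste(bg, list(), sampleInstances(cfg, 1L, c(24L, 24L))[0, ])
  expect_identical(sampleImage(out), bg)
  expect_equal(sum(sampleMask(out)), 0)
})

test_that("identity paste of one cutout reproduces its alpha popcount", {
  cfg <- testFixtureConfig(seed = 8L, size = 48L)
  fr <- makeAnnotatedFrame(cfg)
  cuts <- extractCutouts(fr, minArea = 5L)
  cut <- cuts[[1]]
  bb <- attr(cut, "bbox")
  blank <- array(0.2, c(48, 48, 3))
  inst <- data.frame(cutoutIndex = 1, centerRow = (bb[1] + bb[2]) / 2 - 1,
                     centerCol = (bb[3] + bb[4]) / 2 - 1, scale = 1,
                     rotation = 0, hflip = FALSE, vflip = FALSE)
  out <- renderPaste(blank, list(cut), inst)
  expect_equal(sum(sampleMask(out)), sum(cut@alpha))
  ## exact footprint at the source position
  ref <- matrix(0L, 48, 48)
  ref[bb[1]:bb[2], bb[3]:bb[4]][cut@alpha == 1L] <- 1L
  expect_identical(sampleMask(out), ref)
})

test_that("composite masks equal the per-pixel brute-force coverage oracle", {
  cfg <- testFixtureConfig(seed = 21L, size = 40L)
  fr <- makeAnnotatedFrame(cfg)
  cuts <- extractCutouts(fr, minArea = 5L)
  scfg <- synthesisConfig(nImages = 1L, headsPerImage = c(2L, 5L),
                          scaleRange = c(0.6, 1.5),
                          rotationRange = c(-180, 180), seed = 3L)
  bg <- array(0.3, c(40, 40, 3))
  for (rep in 1:5) {
    inst <- sampleInstances(scfg, length(cuts), c(40L, 40L),
                            seed = 100L + rep)
    out <- renderPaste(bg, cuts, inst)
    expect_identical(sampleMask(out), oracleCoverage(cuts, inst, 40, 40))
  }
})

test_that("instances fully outside the frame contribute nothing", {
  cfg <- testFixtureConfig(seed = 8L, size = 48L)
  cuts <- extractCutouts(makeAnnotatedFrame(cfg), minArea = 5L)
  inst <- data.frame(cutoutIndex = 1, centerRow = 500, centerCol = 500,
                     scale = 1, rotation = 45, hflip = FALSE, vflip = FALSE)
  bg <- array(0.3, c(48, 48, 3))
  out <- renderPaste(bg, cuts, inst)
  expect_identical(sampleImage(out), bg)
  expect_equal(sum(sampleMask(out)), 0)
})

test_that("dataset synthesis is split-correct, binary on reload, reproducible", {
  cfg <- testFixtureConfig(seed = 31L, size = 48L)
  corp <- generateFixtureCorpus(cfg, withr::local_tempdir())
  src <- annotatedSample(readImagePNG(corp$source$image_path[1]),
                         readMaskPNG(corp$source$mask_path[1]))
  cuts <- extractCutouts(src, minArea = 5L)
  scfg <- synthesisConfig(nImages = 10L, headsPerImage = c(2L, 5L),
                          trainFraction = 0.9, seed = 6L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- synthesizeDataset(scfg, cuts, corp$backgrounds, d1)
  m2 <- synthesizeDataset(scfg, cuts, corp$backgrounds, d2)
  expect_equal(sum(m1$split == "train"), 9)
  expect_equal(sum(m1$split == "val"), 1)
  for (p in m1$mask_path)
    expect_true(all(readMaskPNG(p) %in% c(0L, 1L)))
  h <- function(m) unname(tools::md5sum(c(m$image_path, m$mask_path)))
  expect_identical(h(m1), h(m2))
  expect_error(synthesizeDataset(scfg, list(), corp$backgrounds,
                                 withr::local_tempdir()), "empty cutout")
})
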