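randMask <- function(n, p = 0.4) matrix(as.integer(runif(n * n) < p), n, n)

test_that("dice and iou match set-counting oracles on crafted cases", {
  a <- matrix(0L, 4, 4); a[1:2, 1] <- 1L        # |A| = 2
  b <- matrix(0L, 4, 4); b[1, 1] <- 1L          # |B| = 1, overlap 1
  expect_equal(dice(a, b), 2 / 3)
  expect_equal(iou(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  disj <- matrix(0L, 4, 4); disj[4, 4] <- 1L
  expect_equal(dice(a, disj), 0)
  expect_equal(iou(a, disj), 0)
  z <- matrix(0L, 4, 4)
  expect_equal(dice(z, z), 1)                    # both-empty convention
  expect_equal(iou(z, z), 1)
  expect_error(dice(a, matrix(0L, 3, 3)), "dimensions")
  expect_error(iou(a, matrix(2L, 4, 4)), "binary")
})

test_that("dice equals 2*iou/(1+iou) and both match pixel counting", {
  set.seed(55)
  for (rep in 1:100) {
    a <- randMask(9); b <- randMask(9)
    inter <- 0; aOnly <- 0; bOnly <- 0
    for (i in 1:9) for (j in 1:9) {
      if (a[i, j] == 1 && b[i, j] == 1) inter <- inter + 1
      else if (a[i, j] == 1) aOnly <- aOnly + 1
      else if (b[i, j] == 1) bOnly <- bOnly + 1
    }
    dOracle <- if (inter + aOnly + bOnly == 0) 1 else
      2 * inter / (2 * inter + aOnly + bOnly)
    jOracle <- if (inter + aOnly + bOnly == 0) 1 else
      inter / (inter + aOnly + bOnly)
    expect_equal(dice(a, b), dOracle, tolerance = 1e-12)
    expect_equal(iou(a, b), jOracle, tolerance = 1e-12)
    expect_equal(dice(a, b), 2 * iou(a, b) / (1 + iou(a, b)),
                 tolerance = 1e-12)
    expect_lte(iou(a, b), dice(a, b))
  }
})

test_that("reports derive macro means and validate their invariants", {
  per <- data.frame(dice = c(0.8, 0.6, 1.0), iou = c(0.7, 0.5, 1.0))
  r <- metricsReport("B", "internal", perImage = per)
  expect_equal(r@meanDice, 0.8)
  expect_equal(r@meanIoU, mean(c(0.7, 0.5, 1.0)))
  expect_equal(r@nImages, 3L)
  expect_error(new("MetricsReport", modelId = "x", datasetId = "y",
                   meanDice = 1.2, meanIoU = 0.5, nImages = 1L,
                   perImage = data.frame()), "0, 1")
})

test_that("model evaluation averages per-image scores, order-invariantly", {
  corp <- generateFixtureCorpus(
    testFixtureConfig(seed = 61L, size = 32L, nTestFrames = 3L),
    withr::local_tempdir())
  model <- buildUnet(unetSpec(depth = 2L, baseChannels = 4L), seed = 5L)
  r <- evaluateModel(model, corp$test, modelId = "m", datasetId = "t")
  expect_equal(r@nImages, 3L)
  expect_equal(r@meanDice, mean(r@perImage$dice), tolerance = 1e-12)
  expect_equal(r@meanIoU, mean(r@perImage$iou), tolerance = 1e-12)
  rRev <- evaluateModel(model, corp$test[3:1, ], modelId = "m",
                        datasetId = "t")
  expect_equal(rRev@meanDice, r@meanDice, tolerance = 1e-12)
  expect_equal(rRev@meanIoU, r@meanIoU, tolerance = 1e-12)
  ## perfect prediction scores 1 on both metrics
  truth <- readMaskPNG(corp$test$mask_path[1])
  expect_equal(dice(truth, truth), 1)
})

test_that("delta and ratio tables compute at stored precision", {
  mk <- function(id, d, j) metricsReport(id[1], id[2], d, j, 10L)
  earlier <- list(mk(c("A", "x"), 0.50, 0.40), mk(c("A", "y"), 0.30, 0.20))
  later <- list(mk(c("B", "y"), 0.45, 0.28), mk(c("B", "x"), 0.62, 0.51))
  dt <- deltaTable(earlier, later)
  expect_equal(dt$dice_delta_pct[dt$dataset_id == "x"], 12, tolerance = 1e-9)
  expect_equal(dt$iou_delta_pct[dt$dataset_id == "y"], 8, tolerance = 1e-9)
  rt <- ratioTable(earlier, later)
  expect_equal(rt$iou_ratio[rt$dataset_id == "x"], 0.51 / 0.40,
               tolerance = 1e-12)
  ## identical reports: zero delta, unit ratio
  expect_true(all(abs(deltaTable(earlier, earlier)$dice_delta_pct) < 1e-12))
  expect_true(all(abs(ratioTable(earlier, earlier)$iou_ratio - 1) < 1e-12))
  expect_error(deltaTable(earlier, later[1]), "match")
  expect_error(ratioTable(list(mk(c("A", "x"), 0.5, 0)), later[2]), "zero")
})

test_that("rendered reports round-trip through CSV with stable columns", {
  reports <- list(metricsReport("A", "w", 0.709, 0.566, 100L),
                  metricsReport("B", "w", 0.811, 0.686, 100L),
                  metricsReport("A", "g", 0.368, 0.274, 365L))
  csv <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".md")
  long <- renderReport(reports,
                       comparisons = list(deltas = deltaTable(
                         reports[c(1, 3)], list(reports[[2]],
                           metricsReport("B", "g", 0.578, 0.44, 365L)))),
                       outCsv = csv, outMd = md)
  back <- read.csv(csv)
  expect_identical(names(back), c("model_id", "dataset_id", "mean_dice",
                                  "mean_iou", "n_images"))
  expect_equal(back$mean_dice, long$mean_dice, tolerance = 1e-12)
  expect_equal(back$mean_iou, long$mean_iou, tolerance = 1e-12)
  lines <- readLines(md)
  expect_true(any(grepl("w Dice", lines)))
  expect_true(any(grepl("0.709", lines)))
})
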