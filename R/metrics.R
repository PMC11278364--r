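## Dice/IoU metrics, per-dataset evaluation, and comparison tables
## (percentage-point deltas and IoU performance ratios between models).

.checkMaskPair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask dimensions must match")
  if (!all(pred %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L)))
    stop("masks must be strictly binary")
}

#' Dice coefficient between two binary masks
#'
#' 2|A n B| / (|A| + |B|); two empty masks score 1 by convention.
#'
#' @param pred,truth binary matrices of equal dimensions.
#' @return value in \[0, 1\].
#' @export
dice <- function(pred, truth) {
  .checkMaskPair(pred, truth)
  a <- sum(pred); b <- sum(truth)
  if (a + b == 0) return(1)
  2 * sum(pred * truth) / (a + b)
}

#' Intersection-over-union (Jaccard index) between two binary masks
#'
#' |A n B| / |A u B|; two empty masks score 1 by convention.
#'
#' @param pred,truth binary matrices of equal dimensions.
#' @return value in \[0, 1\].
#' @export
iou <- function(pred, truth) {
  .checkMaskPair(pred, truth)
  inter <- sum(pred * truth)
  uni <- sum(pred) + sum(truth) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Evaluate a segmenter on a test manifest
#'
#' Per-image Dice and IoU against the manifest's masks, summarised as
#' unweighted per-image (macro) means.
#'
#' @param model a U-Net model environment.
#' @param test manifest whose rows all carry masks.
#' @param threshold probability threshold for predicted masks.
#' @param modelId,datasetId labels recorded in the report.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, test, threshold = 0.5,
                          modelId = "model", datasetId = "test") {
  validateManifest(test, requireMasks = TRUE)
  if (nrow(test) == 0L) stop("test manifest is empty")
  per <- data.frame(dice = numeric(nrow(test)), iou = numeric(nrow(test)))
  for (i in seq_len(nrow(test))) {
    pair <- .loadPair(test[i, ])
    pr <- predictMask(model, pair$image, threshold)
    per$dice[i] <- dice(pr$mask, pair$mask)
    per$iou[i] <- iou(pr$mask, pair$mask)
  }
  metricsReport(modelId, datasetId, perImage = per)
}

.reportsByDataset <- function(reports) {
  ids <- vapply(reports, function(r) r@datasetId, character(1))
  setNames(reports, ids)
}

#' Percentage-point improvement table between two model evaluations
#'
#' For each dataset present in both sets, computes
#' 100 * (later - earlier) for Dice and IoU at stored precision;
#' display rounding (1 decimal) is applied only by [renderReport()].
#'
#' @param earlier,later lists of [MetricsReport-class] objects with matching
#'   dataset ids.
#' @return data.frame with columns dataset_id, dice_delta_pct, iou_delta_pct.
#' @export
deltaTable <- function(earlier, later) {
  a <- .reportsByDataset(earlier); b <- .reportsByDataset(later)
  if (!setequal(names(a), names(b)))
    stop("dataset ids do not match between the two report sets")
  ids <- names(a)
  data.frame(
    dataset_id = ids,
    dice_delta_pct = vapply(ids, function(i)
      100 * (b[[i]]@meanDice - a[[i]]@meanDice), numeric(1)),
    iou_delta_pct = vapply(ids, function(i)
      100 * (b[[i]]@meanIoU - a[[i]]@meanIoU), numeric(1)),
    row.names = NULL)
}

#' IoU performance-ratio table between a final and a baseline model
#'
#' For each dataset, the final model's IoU divided by the baseline's.
#'
#' @param baseline,final lists of [MetricsReport-class] objects with
#'   matching dataset ids; baseline IoU must be positive.
#' @return data.frame with columns dataset_id, iou_ratio.
#' @export
ratioTable <- function(baseline, final) {
  a <- .reportsByDataset(baseline); b <- .reportsByDataset(final)
  if (!setequal(names(a), names(b)))
    stop("dataset ids do not match between the two report sets")
  ids <- names(a)
  ratios <- vapply(ids, function(i) {
    if (a[[i]]@meanIoU <= 0) stop("baseline IoU is zero for ", i)
    b[[i]]@meanIoU / a[[i]]@meanIoU
  }, numeric(1))
  data.frame(dataset_id = ids, iou_ratio = ratios, row.names = NULL)
}

#' Render an evaluation report as CSV and markdown
#'
#' Writes a long-format CSV (`model_id,dataset_id,mean_dice,mean_iou,
#' n_images`, full precision) and a markdown table with one row per model
#' and Dice/IoU columns per dataset (3 decimals), followed by any
#' comparison tables (deltas to 1 decimal, ratios to 3).
#'
#' @param reports list of [MetricsReport-class] objects.
#' @param comparisons optional named list of data.frames from
#'   [deltaTable()] / [ratioTable()].
#' @param outCsv,outMd output paths (NULL to skip either).
#' @return the long-format data.frame, invisibly.
#' @export
renderReport <- function(reports, comparisons = list(),
                         outCsv = NULL, outMd = NULL) {
  stopifnot(length(reports) >= 1L)
  long <- do.call(rbind, lapply(reports, function(r)
    data.frame(model_id = r@modelId, dataset_id = r@datasetId,
               mean_dice = r@meanDice, mean_iou = r@meanIoU,
               n_images = r@nImages)))
  if (!is.null(outCsv))
    write.csv(long, outCsv, row.names = FALSE, quote = FALSE)
  if (!is.null(outMd)) {
    models <- unique(long$model_id)
    datasets <- unique(long$dataset_id)
    header <- paste0("| Model | ", paste0(
      vapply(datasets, function(d) paste0(d, " Dice | ", d, " IoU"),
             character(1)), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---|", 1 + 2 * length(datasets)),
                             collapse = ""))
    lines <- c(header, sep)
    for (m in models) {
      cells <- unlist(lapply(datasets, function(d) {
        row <- long[long$model_id == m & long$dataset_id == d, ]
        if (nrow(row) == 0) c("-", "-")
        else sprintf("%.3f", c(row$mean_dice, row$mean_iou))
      }))
      lines <- c(lines, paste0("| ", m, " | ",
                               paste(cells, collapse = " | "), " |"))
    }
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      lines <- c(lines, "", paste0("**", nm, "**"), "")
      cols <- names(cmp)
      lines <- c(lines, paste0("| ", paste(cols, collapse = " | "), " |"),
                 paste0("|", paste(rep("---|", length(cols)), collapse = "")))
      for (i in seq_len(nrow(cmp))) {
        vals <- vapply(cols, function(cn) {
          v <- cmp[i, cn]
          if (is.numeric(v)) {
            if (grepl("delta", cn)) sprintf("%.1f", v)
            else sprintf("%.3f", v)
          } else as.character(v)
        }, character(1))
        lines <- c(lines, paste0("| ", paste(vals, collapse = " | "), " |"))
      }
    }
    writeLines(lines, outMd)
  }
  invisible(long)
}
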