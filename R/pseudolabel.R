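## Pseudo-labelling: predict masks for an unlabelled pool, score prediction
## confidence, select the best candidates (the study selected 99 of 360,
## manually; the score here is an automated proxy and a review gallery
## preserves the human-in-the-loop path), and assemble the fine-tuning set.

#' Confidence score of a pseudo-label candidate
#'
#' Half the sum of the mean probability over predicted-foreground pixels
#' and the mean complement probability over predicted-background pixels; a
#' term whose region is empty contributes 0. Confident, well-separated maps
#' score near 1. This is a proxy for the study's manual rule of maximising
#' segmented wheat-head area while minimising segmented background.
#'
#' @param probabilityMap (H, W) matrix in \[0, 1\].
#' @param predictedMask (H, W) binary matrix (the thresholded map).
#' @return score in \[0, 1\].
#' @export
scorePrediction <- function(probabilityMap, predictedMask) {
  if (!identical(dim(probabilityMap), dim(predictedMask)))
    stop("probability map and mask dimensions must match")
  fg <- predictedMask == 1L
  fgTerm <- if (any(fg)) mean(probabilityMap[fg]) else 0
  bgTerm <- if (any(!fg)) mean(1 - probabilityMap[!fg]) else 0
  0.5 * (fgTerm + bgTerm)
}

#' Generate scored pseudo-label candidates for an unlabelled pool
#'
#' Runs the model over every pool row (order preserved), thresholds the
#' probability maps and attaches confidence scores.
#'
#' @param model a trained U-Net model environment.
#' @param pool manifest of unlabelled images.
#' @param threshold probability threshold.
#' @return list of [PseudoCandidate-class] objects.
#' @export
generateCandidates <- function(model, pool, threshold = 0.5) {
  validateManifest(pool)
  out <- vector("list", nrow(pool))
  for (i in seq_len(nrow(pool))) {
    path <- pool$image_path[i]
    if (!file.exists(path))
      stop("cannot read image for pool row ", i, ": ", path)
    img <- readImagePNG(path)
    pr <- predictMask(model, img, threshold)
    out[[i]] <- new("PseudoCandidate", imageRef = path,
                    probabilityMap = pr$probabilities,
                    predictedMask = pr$mask,
                    qualityScore = scorePrediction(pr$probabilities, pr$mask))
  }
  out
}

## deterministic candidate ordering: score descending, then image ref
## ascending (radix sort, locale-independent)
.rankCandidates <- function(candidates) {
  scores <- vapply(candidates, function(c) c@qualityScore, numeric(1))
  refs <- vapply(candidates, function(c) c@imageRef, character(1))
  order(-scores, refs, method = "radix")
}

#' Select pseudo-label candidates and assemble the fine-tuning dataset
#'
#' Applies the selection criterion (top-k, score threshold, or an explicit
#' review list), writes the selected images' predicted masks as PNGs plus a
#' manifest, and emits an HTML contact-sheet gallery of *all* candidates
#' with their scores so a human can audit or override the automated choice.
#'
#' @param candidates non-empty list of [PseudoCandidate-class] objects.
#' @param criterion a [SelectionCriterion-class].
#' @param outDir writable output directory.
#' @return the pseudo-label manifest (also written to
#'   `outDir/delta_pl.csv`); the gallery is `outDir/gallery.html`.
#' @export
selectCandidates <- function(candidates, criterion, outDir) {
  stopifnot(length(candidates) >= 1L)
  validObject(criterion)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ord <- .rankCandidates(candidates)
  refs <- vapply(candidates, function(c) c@imageRef, character(1))
  selIdx <- switch(criterion@mode,
    top_k = {
      if (criterion@k > length(candidates))
        stop("k = ", criterion@k, " exceeds the candidate pool size ",
             length(candidates))
      ord[seq_len(criterion@k)]
    },
    score_threshold = {
      keep <- ord[vapply(ord, function(i)
        candidates[[i]]@qualityScore >= criterion@threshold, logical(1))]
      if (length(keep) == 0L)
        warning("no candidate reaches the score threshold ",
                criterion@threshold)
      keep
    },
    manual_review_list = {
      keep <- ord[refs[ord] %in% criterion@reviewList]
      keep
    })

  ## review gallery over the full pool, mirroring the manual curation step
  mskDir <- file.path(outDir, "msk")
  thumbDir <- file.path(outDir, "thumbs")
  dir.create(mskDir, showWarnings = FALSE)
  dir.create(thumbDir, showWarnings = FALSE)
  gal <- c("<html><head><title>pseudo-label review</title></head><body>",
           "<h1>Pseudo-label candidates (score-ranked)</h1>")
  for (i in ord) {
    cand <- candidates[[i]]
    tp <- file.path(thumbDir, sprintf("cand_%04d.png", i))
    writeMaskPNG(cand@predictedMask, tp)
    gal <- c(gal, sprintf(
      paste0("<div style='display:inline-block;margin:4px'>",
             "<img src='thumbs/%s' width='96'/><br/>%s<br/>score %.4f %s",
             "</div>"),
      basename(tp), basename(cand@imageRef), cand@qualityScore,
      if (i %in% selIdx) "[selected]" else ""))
  }
  gal <- c(gal, "</body></html>")
  writeLines(gal, file.path(outDir, "gallery.html"))

  rows <- lapply(selIdx, function(i) {
    cand <- candidates[[i]]
    mp <- file.path(mskDir, sprintf("pl_%04d.png", i))
    writeMaskPNG(cand@predictedMask, mp)
    newManifest(cand@imageRef, mp, "train")
  })
  manifest <- if (length(rows)) do.call(rbind, rows)
              else newManifest(character(), character(), character())
  writeManifest(manifest, file.path(outDir, "delta_pl.csv"))
  manifest
}
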