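## Shared I/O helpers: 8-bit PNG images, binary mask PNGs, dataset manifests.
## Conventions: images live in memory as (H, W, 3) double arrays in [0, 1];
## masks as (H, W) integer matrices in {0, 1} ({0, 255} on disk).

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Read an RGB image from a PNG file
#'
#' Returns an (H, W, 3) double array in \[0, 1\]. Grayscale files are expanded
#' to three identical channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a PNG file.
#' @return numeric array of dimension H x W x 3.
#' @export
readImagePNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) {
    x <- array(rep(x, 3L), c(dim(x), 3L))
  } else if (dim(x)[3] >= 3L) {
    x <- x[, , 1:3, drop = FALSE]
  } else {
    x <- array(rep(x[, , 1], 3L), c(dim(x)[1:2], 3L))
  }
  x
}

#' Write an RGB image to a PNG file
#'
#' @param image (H, W, 3) array in \[0, 1\]; values are clipped and quantised
#'   to 8 bits.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' Read a binary mask from a PNG file
#'
#' Disk values are {0, 255} (or any 8-bit grayscale, thresholded at 0.5);
#' the in-memory representation is an integer matrix in {0, 1}.
#'
#' @param path path to a single-channel PNG file.
#' @return integer matrix in {0, 1}.
#' @export
readMaskPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(x >= 0.5), nrow(x), ncol(x))
  m
}

#' Write a binary mask to a PNG file
#'
#' @param mask matrix in {0, 1} (foreground stored as 255 on disk).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  stopifnot(is.matrix(mask))
  v <- as.numeric(mask)
  if (!all(v %in% c(0, 1))) stop("mask must be strictly binary")
  png::writePNG(matrix(v, nrow(mask), ncol(mask)), path)
  invisible(path)
}

assertBinaryMask <- function(mask, what = "mask") {
  if (!is.matrix(mask)) stop(what, " must be a matrix")
  if (!all(mask %in% c(0L, 1L))) stop(what, " must be strictly binary (0/1)")
  invisible(TRUE)
}

## ---- dataset manifests -----------------------------------------------------

manifestColumns <- c("image_path", "mask_path", "split")

#' Create a dataset manifest
#'
#' A manifest is a plain data.frame with character columns `image_path`,
#' `mask_path` and `split`. Unlabelled rows carry an empty `mask_path`.
#'
#' @param image_path,mask_path,split character vectors of equal length
#'   (`mask_path` and `split` are recycled if length 1).
#' @return a manifest data.frame.
#' @export
newManifest <- function(image_path, mask_path = "", split = "train") {
  data.frame(image_path = as.character(image_path),
             mask_path = as.character(mask_path),
             split = as.character(split),
             stringsAsFactors = FALSE)
}

#' Validate a dataset manifest
#'
#' @param manifest a manifest data.frame.
#' @param requireMasks if TRUE, every row must name a mask file.
#' @return the manifest, invisibly.
#' @export
validateManifest <- function(manifest, requireMasks = FALSE) {
  if (!is.data.frame(manifest) || !all(manifestColumns %in% names(manifest)))
    stop("manifest must be a data.frame with columns ",
         paste(manifestColumns, collapse = ", "))
  if (requireMasks && any(is.na(manifest$mask_path) | manifest$mask_path == ""))
    stop("manifest has rows with empty mask_path where masks are required")
  invisible(manifest)
}

#' Read a manifest CSV
#'
#' @param path CSV file with header `image_path,mask_path,split`.
#' @return a manifest data.frame.
#' @export
readManifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df$mask_path[is.na(df$mask_path)] <- ""
  validateManifest(df)
  df
}

#' Write a manifest CSV
#'
#' @param manifest a manifest data.frame.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  validateManifest(manifest)
  write.csv(manifest[, manifestColumns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Derive a bounded child seed from a base seed and a stream index, so that
## every frame/sample gets its own reproducible RNG state.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 2654435) %%
               2147480009)
}
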