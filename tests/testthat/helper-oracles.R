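## Independent oracles used across the suite. These are deliberately
## written as scalar loops / alternative formulations, separate from the
## package's vectorised implementations.

## Small fixture configuration used throughout the tests.
testFixtureConfig <- function(seed = 1L, size = 64L, ...) {
  defaults <- list(seed = seed, imageHeight = size, imageWidth = size,
                   blobsPerFrame = c(4L, 9L), blobAxes = c(4, 10),
                   nBackgroundFrames = 3L, nRealFrames = 3L,
                   nTestFrames = 2L)
  do.call(fixtureConfig, utils::modifyList(defaults, list(...)))
}

## Point-in-ellipse test over the full frame, scalar per pixel.
oracleEllipseMask <- function(blobs, H, W) {
  m <- matrix(0L, H, W)
  for (i in seq_len(nrow(blobs))) {
    b <- blobs[i, ]
    for (r in 1:H) for (cc in 1:W) {
      dy <- r - b$cy; dx <- cc - b$cx
      u <- dy * cos(b$theta) + dx * sin(b$theta)
      v <- -dy * sin(b$theta) + dx * cos(b$theta)
      if ((u / b$a)^2 + (v / b$b)^2 <= 1) m[r, cc] <- 1L
    }
  }
  m
}

## Queue-based connected-component count with selectable connectivity.
oracleComponentCount <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  if (connectivity == 8) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0L
  for (r in 1:H) for (cc in 1:W) {
    if (mask[r, cc] == 1L && !seen[r, cc]) {
      count <- count + 1L
      queue <- list(c(r, cc)); seen[r, cc] <- TRUE
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          nr <- p[1] + nb[k, 1]; nc <- p[2] + nb[k, 2]
          if (nr >= 1 && nr <= H && nc >= 1 && nc <= W &&
              mask[nr, nc] == 1L && !seen[nr, nc]) {
            seen[nr, nc] <- TRUE
            queue[[length(queue) + 1]] <- c(nr, nc)
          }
        }
      }
    }
  }
  count
}

## Per-pixel coverage map of paste instances: for every frame pixel,
## inverse-transform into each cutout's patch frame, bilinearly sample the
## alpha as a scalar sum over the four neighbours, binarise at 0.5, union.
oracleCoverage <- function(cutouts, instances, H, W) {
  m <- matrix(0L, H, W)
  for (t in seq_len(nrow(instances))) {
    inst <- instances[t, ]
    cut <- cutouts[[inst$cutoutIndex]]
    h <- nrow(cut@alpha); w <- ncol(cut@alpha)
    phi <- inst$rotation * pi / 180
    for (r in 1:H) for (cc in 1:W) {
      gr <- (r - 1) - inst$centerRow
      gc <- (cc - 1) - inst$centerCol
      sr <- (cos(phi) * gr + sin(phi) * gc) / inst$scale + (h - 1) / 2
      sc <- (-sin(phi) * gr + cos(phi) * gc) / inst$scale + (w - 1) / 2
      if (isTRUE(inst$hflip)) sc <- (w - 1) - sc
      if (isTRUE(inst$vflip)) sr <- (h - 1) - sr
      i0 <- floor(sr); j0 <- floor(sc); fi <- sr - i0; fj <- sc - j0
      a <- 0
      for (di in 0:1) for (dj in 0:1) {
        ii <- i0 + di; jj <- j0 + dj
        if (ii >= 0 && ii < h && jj >= 0 && jj < w) {
          wt <- (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
          a <- a + wt * cut@alpha[ii + 1, jj + 1]
        }
      }
      if (a >= 0.5) m[r, cc] <- 1L
    }
  }
  m
}

## Independent hue rotation: max/min-based RGB->HSV and sector-free
## HSV->RGB through hue distance to the R/G/B anchors.
oracleHueRotate <- function(image, degrees) {
  d <- dim(image)
  out <- image
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    px <- image[r, cc, ]
    mx <- max(px); mn <- min(px); delta <- mx - mn
    v <- mx
    s <- if (mx > 0) delta / mx else 0
    h <- 0
    if (delta > 0) {
      if (mx == px[1]) h <- ((px[2] - px[3]) / delta) %% 6
      else if (mx == px[2]) h <- (px[3] - px[1]) / delta + 2
      else h <- (px[1] - px[2]) / delta + 4
      h <- h / 6
    }
    h <- (h + degrees / 360) %% 1
    ## HSV -> RGB via the k-formula (alternative to the chroma sectors)
    f <- function(n) {
      k <- (n + h * 6) %% 6
      v - v * s * max(0, min(k, 4 - k, 1))
    }
    out[r, cc, ] <- c(f(5), f(3), f(1))
  }
  out
}

## Scaled-down cut-and-paste corpus shared by GAN-related tests.
makeTinyPairs <- function(n, seed = 1L, size = 32L) {
  cfg <- testFixtureConfig(seed = seed, size = size)
  lapply(seq_len(n), function(i) {
    s <- makeAnnotatedFrame(cfg, seed = seed * 1000L + i)
    list(S = domainSampleS(sampleImage(s), sampleMask(s)),
         R = domainSampleR(makeRealDomainFrame(cfg, seed = seed * 2000L + i)))
  })
}
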