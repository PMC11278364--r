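## Network architectures. The translation generators follow the canonical
## unpaired-translation recipe: a 7x7 reflection-padded stem, two stride-2
## downsampling convolutions, residual blocks at the bottleneck, two
## nearest-upsample+conv stages and a 7x7 tanh head. Discriminators are
## patch-level least-squares classifiers. The segmenter is a standard
## U-Net with maxpool downsampling, bilinear upsampling and a sigmoid
## per-pixel probability head.

## residual encoder-decoder generator; input dims must be divisible by 4
resnetGenerator <- function(cin, cout, base = 32L, nres = 6L) {
  layers <- list(
    nnConv(cin, base, 7L, pad = 3L, padMode = "reflect"),
    nnInstNorm(base), nnAct("relu"),
    nnConv(base, 2L * base, 3L, stride = 2L, pad = 1L),
    nnInstNorm(2L * base), nnAct("relu"),
    nnConv(2L * base, 4L * base, 3L, stride = 2L, pad = 1L),
    nnInstNorm(4L * base), nnAct("relu"))
  for (i in seq_len(nres)) layers <- c(layers, list(nnResBlock(4L * base)))
  layers <- c(layers, list(
    nnUpsample("nearest"),
    nnConv(4L * base, 2L * base, 3L, pad = 1L),
    nnInstNorm(2L * base), nnAct("relu"),
    nnUpsample("nearest"),
    nnConv(2L * base, base, 3L, pad = 1L),
    nnInstNorm(base), nnAct("relu"),
    nnConv(base, cout, 7L, pad = 3L, padMode = "reflect"),
    nnAct("tanh")))
  g <- do.call(nnSeq, layers)
  g$cin <- as.integer(cin); g$cout <- as.integer(cout)
  g
}

## Patch-level discriminator emitting an (H', W', 1) score map (no sigmoid;
## least-squares adversarial loss). Deliberately un-normalised: instance
## normalisation inside a discriminator cancels per-channel means, leaving
## it blind to exactly the global colour statistics that separate a
## synthetic domain from a real one — under that blindness the generator's
## colour mapping is unconstrained and can settle on an inverted
## foreground/background polarity.
patchDiscriminator <- function(cin, base = 32L) {
  d <- nnSeq(
    nnConv(cin, base, 4L, stride = 2L, pad = 1L), nnAct("lrelu"),
    nnConv(base, 2L * base, 4L, stride = 2L, pad = 1L), nnAct("lrelu"),
    nnConv(2L * base, 4L * base, 4L, stride = 1L, pad = 1L), nnAct("lrelu"),
    nnConv(4L * base, 1L, 4L, stride = 1L, pad = 1L))
  d$cin <- as.integer(cin)
  d
}

## ---- U-Net -----------------------------------------------------------------

.unetConvBlock <- function(cin, cout, norm = "none") {
  if (norm == "instance")
    nnSeq(nnConv(cin, cout, 3L, pad = 1L, init = "he"), nnInstNorm(cout),
          nnAct("relu"),
          nnConv(cout, cout, 3L, pad = 1L, init = "he"), nnInstNorm(cout),
          nnAct("relu"))
  else
    nnSeq(nnConv(cin, cout, 3L, pad = 1L, init = "he"), nnAct("relu"),
          nnConv(cout, cout, 3L, pad = 1L, init = "he"), nnAct("relu"))
}

nnUNet <- function(spec) {
  D <- spec@depth; base <- spec@baseChannels; nrm <- spec@norm
  ch <- base * 2^(seq_len(D) - 1)              # channels per level
  enc <- vector("list", D); pools <- vector("list", D)
  ups <- vector("list", D); upconvs <- vector("list", D)
  dec <- vector("list", D)
  for (d in seq_len(D)) {
    enc[[d]] <- .unetConvBlock(if (d == 1L) spec@inChannels else ch[d - 1],
                               ch[d], nrm)
    pools[[d]] <- nnMaxPool()
    ups[[d]] <- nnUpsample("bilinear")
    upconvs[[d]] <- nnConv(2L * ch[d], ch[d], 3L, pad = 1L, init = "he")
    dec[[d]] <- .unetConvBlock(2L * ch[d], ch[d], nrm)
  }
  bottleneck <- .unetConvBlock(ch[D], 2L * ch[D], nrm)
  final <- nnConv(ch[1], spec@outChannels, 1L, init = "he")
  outAct <- nnAct("sigmoid")
  m <- .newLayer("unet", depth = D, skipCh = ch,
                 enc = enc, pools = pools, bottleneck = bottleneck,
                 ups = ups, upconvs = upconvs, dec = dec,
                 final = final, outAct = outAct)
  m$modules <- c(enc, pools, list(bottleneck), ups, upconvs, dec,
                 list(final, outAct))
  m$spec <- spec
  m
}

.fwdUNet <- function(m, x, train) {
  d <- dim(x)
  if (d[1] %% 2^m$depth != 0L || d[2] %% 2^m$depth != 0L)
    stop("input dimensions (", d[1], "x", d[2],
         ") must be divisible by 2^depth = ", 2^m$depth)
  skips <- vector("list", m$depth)
  for (lev in seq_len(m$depth)) {
    x <- netForward(m$enc[[lev]], x, train)
    skips[[lev]] <- x
    x <- netForward(m$pools[[lev]], x, train)
  }
  x <- netForward(m$bottleneck, x, train)
  for (lev in rev(seq_len(m$depth))) {
    x <- netForward(m$ups[[lev]], x, train)
    x <- netForward(m$upconvs[[lev]], x, train)
    sk <- skips[[lev]]
    xc <- array(c(sk, x), c(dim(sk)[1], dim(sk)[2],
                            dim(sk)[3] + dim(x)[3]))
    x <- netForward(m$dec[[lev]], xc, train)
  }
  x <- netForward(m$final, x, train)
  netForward(m$outAct, x, train)
}

.bwdUNet <- function(m, gy) {
  g <- netBackward(m$outAct, gy)
  g <- netBackward(m$final, g)
  gskips <- vector("list", m$depth)
  for (lev in seq_len(m$depth)) {               # reverse of decoder order
    g <- netBackward(m$dec[[lev]], g)
    nsk <- m$skipCh[lev]
    gskips[[lev]] <- g[, , seq_len(nsk), drop = FALSE]
    gup <- g[, , nsk + seq_len(dim(g)[3] - nsk), drop = FALSE]
    g <- netBackward(m$upconvs[[lev]], gup)
    g <- netBackward(m$ups[[lev]], g)
  }
  g <- netBackward(m$bottleneck, g)
  for (lev in rev(seq_len(m$depth))) {          # reverse of encoder order
    g <- netBackward(m$pools[[lev]], g)
    g <- g + gskips[[lev]]
    g <- netBackward(m$enc[[lev]], g)
  }
  g
}
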