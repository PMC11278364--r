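## Minimal CPU neural-network engine used by the GAN and the segmenter.
##
## Tensors are plain (H, W, C) double arrays. Layers and containers are
## mutable environments with a $type tag; netForward()/netBackward()
## dispatch on it. Every layer keeps a *stack* of forward caches: a module
## that is forwarded k times before backpropagation (the CycleGAN
## generators run twice per cycle) must receive its k backward calls in
## reverse forward order, each popping one cache. Inference passes
## (train = FALSE) push nothing.
##
## Convolution is im2col (C++) + BLAS GEMM; its adjoint is col2im.
## Gradients accumulate into $g* fields until zeroGrads() resets them.

.newLayer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$cache <- list()
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

.pushCache <- function(l, cc) l$cache[[length(l$cache) + 1L]] <- cc

.popCache <- function(l) {
  n <- length(l$cache)
  if (n == 0L) stop("backward called on layer '", l$type, "' with no cache")
  cc <- l$cache[[n]]
  l$cache[[n]] <- NULL
  cc
}

## ---- convolution -----------------------------------------------------------

#' Create a 2-D convolution layer
#'
#' Weights are stored as a (outChannels x inChannels*k*k) matrix acting on
#' im2col patches. `init = "gauss"` draws N(0, 0.02) weights (the CycleGAN
#' convention); `init = "he"` scales by sqrt(2 / fan-in) (ReLU networks).
#'
#' @param cin,cout input/output channels.
#' @param k kernel size.
#' @param stride stride.
#' @param pad padding width.
#' @param padMode "zero" or "reflect".
#' @param init "gauss" or "he".
#' @return a layer environment.
#' @keywords internal
nnConv <- function(cin, cout, k, stride = 1L, pad = 0L,
                   padMode = c("zero", "reflect"), init = c("gauss", "he")) {
  padMode <- match.arg(padMode)
  init <- match.arg(init)
  sd <- if (init == "gauss") 0.02 else sqrt(2 / (cin * k * k))
  .newLayer("conv",
            W = matrix(rnorm(cout * cin * k * k, 0, sd), cout, cin * k * k),
            b = numeric(cout), gW = matrix(0, cout, cin * k * k),
            gb = numeric(cout), k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), padMode = padMode, cin = as.integer(cin))
}

.reflectIdx <- function(n, p) c((p + 1):2, 1:n, (n - 1):(n - p))

.reflectPad <- function(x, p) {
  d <- dim(x)
  x[.reflectIdx(d[1], p), .reflectIdx(d[2], p), , drop = FALSE]
}

.reflectPadBwd <- function(g, p, H, W) {
  d <- dim(g)                                  # (H+2p, W+2p, C)
  m <- rowsum(matrix(g, d[1], d[2] * d[3]), .reflectIdx(H, p))
  a <- array(m, c(H, d[2], d[3]))
  m2 <- rowsum(matrix(aperm(a, c(2, 1, 3)), d[2], H * d[3]), .reflectIdx(W, p))
  aperm(array(m2, c(W, H, d[3])), c(2, 1, 3))
}

.fwdConv <- function(l, x, train) {
  if (l$padMode == "reflect" && l$pad > 0L) {
    xp <- .reflectPad(x, l$pad); p <- 0L
  } else {
    xp <- x; p <- l$pad
  }
  d <- dim(xp)
  cols <- .cpp_im2col(xp, d[1], d[2], d[3], l$k, l$stride, p)
  Ho <- (d[1] + 2L * p - l$k) %/% l$stride + 1L
  Wo <- (d[2] + 2L * p - l$k) %/% l$stride + 1L
  out <- l$W %*% cols + l$b
  if (train)
    .pushCache(l, list(cols = cols, dimIn = dim(x), dimPad = d, p = p,
                       Ho = Ho, Wo = Wo))
  array(t(out), c(Ho, Wo, nrow(l$W)))
}

.bwdConv <- function(l, gy) {
  cc <- .popCache(l)
  cout <- nrow(l$W)
  gmat <- t(matrix(gy, cc$Ho * cc$Wo, cout))
  l$gW <- l$gW + gmat %*% t(cc$cols)
  l$gb <- l$gb + rowSums(gmat)
  gcols <- crossprod(l$W, gmat)
  gxp <- .cpp_col2im(gcols, cc$dimPad[1], cc$dimPad[2], cc$dimPad[3],
                     l$k, l$stride, cc$p)
  if (l$padMode == "reflect" && l$pad > 0L)
    .reflectPadBwd(gxp, l$pad, cc$dimIn[1], cc$dimIn[2])
  else gxp
}

## ---- instance normalisation ------------------------------------------------

nnInstNorm <- function(ch) {
  .newLayer("instnorm", gamma = rep(1, ch), beta = rep(0, ch),
            gGamma = rep(0, ch), gBeta = rep(0, ch), eps = 1e-5)
}

.fwdInstNorm <- function(l, x, train) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + l$eps)
  xhat <- xc * rep(invstd, each = n)
  y <- xhat * rep(l$gamma, each = n) + rep(l$beta, each = n)
  if (train) .pushCache(l, list(xhat = xhat, invstd = invstd, d = d))
  array(y, d)
}

.bwdInstNorm <- function(l, gy) {
  cc <- .popCache(l)
  d <- cc$d; n <- d[1] * d[2]
  gym <- matrix(gy, n, d[3])
  l$gGamma <- l$gGamma + colSums(gym * cc$xhat)
  l$gBeta <- l$gBeta + colSums(gym)
  gxh <- gym * rep(l$gamma, each = n)
  mg <- colMeans(gxh)
  mgx <- colMeans(gxh * cc$xhat)
  gx <- (gxh - rep(mg, each = n) - cc$xhat * rep(mgx, each = n)) *
    rep(cc$invstd, each = n)
  array(gx, d)
}

## ---- activations -----------------------------------------------------------

nnAct <- function(kind = c("relu", "lrelu", "tanh", "sigmoid"),
                  slope = 0.2) {
  .newLayer("act", kind = match.arg(kind), slope = slope)
}

.fwdAct <- function(l, x, train) {
  y <- switch(l$kind,
    relu = pmax(x, 0),
    lrelu = { y <- x; neg <- x < 0; y[neg] <- l$slope * x[neg]; y },
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)))
  if (train)
    .pushCache(l, switch(l$kind,
      relu = , lrelu = list(pos = x >= 0, d = dim(x)),
      list(y = y)))
  y
}

.bwdAct <- function(l, gy) {
  cc <- .popCache(l)
  switch(l$kind,
    relu = gy * cc$pos,
    lrelu = gy * (cc$pos + l$slope * (1 - cc$pos)),
    tanh = gy * (1 - cc$y^2),
    sigmoid = gy * cc$y * (1 - cc$y))
}

## ---- 2x upsampling and 2x2 max pooling ------------------------------------

nnUpsample <- function(mode = c("nearest", "bilinear")) {
  .newLayer("upsample", mode = match.arg(mode))
}

## half-pixel-centre linear map for exact factor-2 upsampling
.linUpMap <- function(n) {
  src <- (0:(2 * n - 1)) / 2 - 0.25
  lo <- floor(src)
  w <- src - lo
  list(lo = pmin(pmax(lo, 0), n - 1) + 1L,
       hi = pmin(pmax(lo + 1, 0), n - 1) + 1L, w = w)
}

.scatterAdd <- function(mat, groups, n) {
  rs <- rowsum(mat, groups)
  out <- matrix(0, n, ncol(mat))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

.fwdUpsample <- function(l, x, train) {
  d <- dim(x)
  if (train) .pushCache(l, list(d = d))
  if (l$mode == "nearest") {
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
      drop = FALSE]
  } else {
    mr <- .linUpMap(d[1]); mc <- .linUpMap(d[2])
    y1 <- x[mr$lo, , , drop = FALSE] * (1 - mr$w) +
          x[mr$hi, , , drop = FALSE] * mr$w
    y1[, mc$lo, , drop = FALSE] * rep(1 - mc$w, each = 2 * d[1]) +
      y1[, mc$hi, , drop = FALSE] * rep(mc$w, each = 2 * d[1])
  }
}

.bwdUpsample <- function(l, gy) {
  d <- .popCache(l)$d
  H <- d[1]; W <- d[2]; C <- d[3]
  if (l$mode == "nearest") {
    m <- rowsum(matrix(gy, 2 * H, 2 * W * C), rep(seq_len(H), each = 2))
    a <- array(m, c(H, 2 * W, C))
    m2 <- rowsum(matrix(aperm(a, c(2, 1, 3)), 2 * W, H * C),
                 rep(seq_len(W), each = 2))
    aperm(array(m2, c(W, H, C)), c(2, 1, 3))
  } else {
    mr <- .linUpMap(H); mc <- .linUpMap(W)
    ## adjoint over columns first
    gm <- matrix(aperm(gy, c(2, 1, 3)), 2 * W, 2 * H * C)
    gcols <- .scatterAdd(rbind(gm * (1 - mc$w), gm * mc$w),
                         c(mc$lo, mc$hi), W)
    g1 <- aperm(array(gcols, c(W, 2 * H, C)), c(2, 1, 3))
    ## then over rows
    grows <- .scatterAdd(rbind(matrix(g1, 2 * H, W * C) * (1 - mr$w),
                               matrix(g1, 2 * H, W * C) * mr$w),
                         c(mr$lo, mr$hi), H)
    array(grows, c(H, W, C))
  }
}

nnMaxPool <- function() .newLayer("maxpool")

.fwdMaxPool <- function(l, x, train) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L)
    stop("max pooling requires even spatial dimensions, got ",
         d[1], "x", d[2])
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  a <- array(x, c(2, H2, d[2], d[3]))
  a1 <- array(a[1, , , , drop = FALSE], c(H2, d[2], d[3]))
  a2 <- array(a[2, , , , drop = FALSE], c(H2, d[2], d[3]))
  m1 <- a1 >= a2                                # ties to the first element
  y1 <- a1 * m1 + a2 * !m1
  b <- array(y1, c(H2, 2, W2, d[3]))
  b1 <- array(b[, 1, , , drop = FALSE], c(H2, W2, d[3]))
  b2 <- array(b[, 2, , , drop = FALSE], c(H2, W2, d[3]))
  m2 <- b1 >= b2
  y <- b1 * m2 + b2 * !m2
  if (train) .pushCache(l, list(m1 = m1, m2 = m2, d = d))
  y
}

.bwdMaxPool <- function(l, gy) {
  cc <- .popCache(l)
  d <- cc$d; H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  gB <- array(0, c(H2, 2, W2, d[3]))
  gB[, 1, , ] <- gy * cc$m2
  gB[, 2, , ] <- gy * !cc$m2
  g1 <- array(gB, c(H2, d[2], d[3]))
  gA <- array(0, c(2, H2, d[2], d[3]))
  gA[1, , , ] <- g1 * cc$m1
  gA[2, , , ] <- g1 * !cc$m1
  array(gA, d)
}

## ---- containers ------------------------------------------------------------

nnSeq <- function(...) .newLayer("seq", layers = list(...))

## residual block: x + IN(conv(relu(IN(conv(x))))), reflection padding
nnResBlock <- function(ch) {
  .newLayer("res", body = nnSeq(
    nnConv(ch, ch, 3L, pad = 1L, padMode = "reflect"),
    nnInstNorm(ch), nnAct("relu"),
    nnConv(ch, ch, 3L, pad = 1L, padMode = "reflect"),
    nnInstNorm(ch)))
}

#' Forward pass through a network module
#'
#' @param m a layer/container environment.
#' @param x (H, W, C) input array.
#' @param train if TRUE, caches are pushed for a later backward pass.
#' @return the output array.
#' @keywords internal
netForward <- function(m, x, train = TRUE) {
  switch(m$type,
    conv = .fwdConv(m, x, train),
    instnorm = .fwdInstNorm(m, x, train),
    act = .fwdAct(m, x, train),
    upsample = .fwdUpsample(m, x, train),
    maxpool = .fwdMaxPool(m, x, train),
    seq = { for (l in m$layers) x <- netForward(l, x, train); x },
    res = x + netForward(m$body, x, train),
    unet = .fwdUNet(m, x, train),
    stop("unknown module type: ", m$type))
}

#' Backward pass through a network module
#'
#' Pops the most recent forward cache; call once per forward pass, in
#' reverse forward order. Parameter gradients accumulate in the layers.
#'
#' @param m a layer/container environment.
#' @param gy gradient of the loss w.r.t. the module output.
#' @return gradient w.r.t. the module input.
#' @keywords internal
netBackward <- function(m, gy) {
  switch(m$type,
    conv = .bwdConv(m, gy),
    instnorm = .bwdInstNorm(m, gy),
    act = .bwdAct(m, gy),
    upsample = .bwdUpsample(m, gy),
    maxpool = .bwdMaxPool(m, gy),
    seq = { for (l in rev(m$layers)) gy <- netBackward(l, gy); gy },
    res = gy + netBackward(m$body, gy),
    unet = .bwdUNet(m, gy),
    stop("unknown module type: ", m$type))
}

## ---- parameters and optimizers --------------------------------------------

nnParams <- function(m) {
  switch(m$type,
    conv = list(list(env = m, w = "W", g = "gW"),
                list(env = m, w = "b", g = "gb")),
    instnorm = list(list(env = m, w = "gamma", g = "gGamma"),
                    list(env = m, w = "beta", g = "gBeta")),
    seq = do.call(c, lapply(m$layers, nnParams)),
    res = nnParams(m$body),
    unet = do.call(c, lapply(m$modules, nnParams)),
    list())
}

zeroGrads <- function(params) {
  for (p in params) p$env[[p$g]] <- p$env[[p$w]] * 0
  invisible(NULL)
}

paramsSnapshot <- function(params) lapply(params, function(p) p$env[[p$w]])

paramsRestore <- function(params, snapshot) {
  for (i in seq_along(params))
    params[[i]]$env[[params[[i]]$w]] <- snapshot[[i]]
  invisible(NULL)
}

## drop all pending forward caches (e.g. after an aborted pass)
clearCaches <- function(m) {
  m$cache <- list()
  switch(m$type,
    seq = for (l in m$layers) clearCaches(l),
    res = clearCaches(m$body),
    unet = for (l in m$modules) clearCaches(l),
    invisible(NULL))
  invisible(NULL)
}

## rescale all gradients so their global L2 norm is at most maxNorm
clipGradNorm <- function(params, maxNorm) {
  if (!is.finite(maxNorm)) return(invisible(NULL))
  total <- sqrt(sum(vapply(params, function(p) sum(p$env[[p$g]]^2),
                           numeric(1))))
  if (total > maxNorm)
    for (p in params) p$env[[p$g]] <- p$env[[p$g]] * (maxNorm / total)
  invisible(NULL)
}

optAdam <- function(params, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$type <- "adam"; e$params <- params; e$lr <- lr
  e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps; e$t <- 0L
  e$m <- lapply(params, function(p) p$env[[p$w]] * 0)
  e$v <- lapply(params, function(p) p$env[[p$w]] * 0)
  e
}

optSGD <- function(params, lr, momentum = 0, weightDecay = 0) {
  e <- new.env(parent = emptyenv())
  e$type <- "sgd"; e$params <- params; e$lr <- lr
  e$momentum <- momentum; e$weightDecay <- weightDecay
  e$vel <- lapply(params, function(p) p$env[[p$w]] * 0)
  e
}

optStep <- function(opt) {
  if (opt$type == "adam") {
    opt$t <- opt$t + 1L
    bc1 <- 1 - opt$beta1^opt$t
    bc2 <- 1 - opt$beta2^opt$t
    for (i in seq_along(opt$params)) {
      p <- opt$params[[i]]
      g <- p$env[[p$g]]
      opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
      opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
      p$env[[p$w]] <- p$env[[p$w]] -
        opt$lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    }
  } else {
    for (i in seq_along(opt$params)) {
      p <- opt$params[[i]]
      g <- p$env[[p$g]] + opt$weightDecay * p$env[[p$w]]
      opt$vel[[i]] <- opt$momentum * opt$vel[[i]] + g
      p$env[[p$w]] <- p$env[[p$w]] - opt$lr * opt$vel[[i]]
    }
  }
  invisible(NULL)
}
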