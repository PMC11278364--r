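## The tensor engine behind the GAN and the segmenter: convolution against
## a direct sliding-window oracle, every backward pass against numerical
## differentiation, and the optimizer update rules against hand arithmetic.

mc <- asNamespace("maskcycle")

naiveConv <- function(x, W, b, k, stride, pad) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2 * pad, Wd + 2 * pad, C))
  xp[pad + 1:H, pad + 1:Wd, ] <- x
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (Wd + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, nrow(W)))
  for (co in seq_len(nrow(W))) for (ho in 1:Ho) for (wo in 1:Wo) {
    s <- b[co]
    for (c in 1:C) for (dx in 1:k) for (dy in 1:k) {
      widx <- (c - 1) * k * k + (dx - 1) * k + dy
      s <- s + W[co, widx] *
        xp[(ho - 1) * stride + dy, (wo - 1) * stride + dx, c]
    }
    out[ho, wo, co] <- s
  }
  out
}

test_that("convolution forward matches a sliding-window oracle", {
  set.seed(11)
  for (cfg in list(list(k = 3, s = 1, p = 1), list(k = 3, s = 2, p = 1),
                   list(k = 4, s = 2, p = 1), list(k = 1, s = 1, p = 0))) {
    x <- array(rnorm(8 * 7 * 2), c(8, 7, 2))
    l <- mc$nnConv(2, 3, cfg$k, stride = cfg$s, pad = cfg$p)
    y <- mc$netForward(l, x, train = FALSE)
    expect_equal(y, naiveConv(x, l$W, l$b, cfg$k, cfg$s, cfg$p),
                 tolerance = 1e-12)
  }
})

test_that("backward passes match numerical gradients through a mixed stack", {
  set.seed(12)
  net <- mc$nnSeq(
    mc$nnConv(2, 3, 3, stride = 1, pad = 1, padMode = "reflect"),
    mc$nnInstNorm(3), mc$nnAct("lrelu"),
    mc$nnUpsample("bilinear"), mc$nnMaxPool(),
    mc$nnConv(3, 4, 3, stride = 2, pad = 1), mc$nnAct("relu"),
    mc$nnUpsample("nearest"),
    mc$nnConv(4, 1, 3, stride = 1, pad = 1), mc$nnAct("sigmoid"))
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  tgt <- array(runif(6 * 6), c(6, 6, 1))
  lossOf <- function() sum((mc$netForward(net, x, train = FALSE) - tgt)^2)
  params <- mc$nnParams(net)
  mc$zeroGrads(params)
  y <- mc$netForward(net, x, train = TRUE)
  gx <- mc$netBackward(net, 2 * (y - tgt))
  numGrad <- function(get, set) {
    eps <- 1e-6
    v0 <- get(); g <- v0 * 0
    for (i in seq_along(v0)) {
      vp <- v0; vp[i] <- vp[i] + eps; set(vp); lp <- lossOf()
      vm <- v0; vm[i] <- vm[i] - eps; set(vm); lm <- lossOf()
      g[i] <- (lp - lm) / (2 * eps)
    }
    set(v0); g
  }
  gxn <- numGrad(function() x, function(v) x <<- v)
  expect_lt(max(abs(gx - gxn)), 1e-6)
  for (p in params) {
    gn <- numGrad(function() p$env[[p$w]], function(v) p$env[[p$w]] <- v)
    expect_lt(max(abs(p$env[[p$g]] - gn)), 1e-6)
  }
})

test_that("residual blocks backpropagate through both branches", {
  set.seed(13)
  net <- mc$nnResBlock(2L)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  lossOf <- function() sum(mc$netForward(net, x, train = FALSE)^2)
  params <- mc$nnParams(net)
  mc$zeroGrads(params)
  y <- mc$netForward(net, x, train = TRUE)
  gx <- mc$netBackward(net, 2 * y)
  eps <- 1e-6
  gn <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    x0 <- x; x <- xp; lp <- lossOf(); x <- xm; lm <- lossOf(); x <- x0
    gn[i] <- (lp - lm) / (2 * eps)
  }
  expect_lt(max(abs(gx - gn)), 1e-6)
})

test_that("bilinear upsampling doubles dims and preserves constants", {
  l <- mc$nnUpsample("bilinear")
  x <- array(2.5, c(3, 5, 2))
  y <- mc$netForward(l, x, train = FALSE)
  expect_equal(dim(y), c(6L, 10L, 2L))
  expect_true(all(abs(y - 2.5) < 1e-12))
  ln <- mc$nnUpsample("nearest")
  x <- array(seq_len(4), c(2, 2, 1))
  yn <- mc$netForward(ln, x, train = FALSE)
  expect_equal(yn[1:2, 1:2, 1], matrix(1, 2, 2))
})

test_that("max pooling selects block maxima and routes gradients to them", {
  l <- mc$nnMaxPool()
  x <- array(0, c(4, 4, 1))
  x[, , 1] <- matrix(c(1, 2, 5, 6,
                       3, 4, 7, 8,
                       9, 10, 13, 14,
                       11, 12, 15, 16), 4, 4, byrow = TRUE)
  y <- mc$netForward(l, x, train = TRUE)
  expect_equal(y[, , 1], matrix(c(4, 8, 12, 16), 2, 2, byrow = TRUE))
  g <- mc$netBackward(l, array(1, c(2, 2, 1)))
  expect_equal(sum(g), 4)
  expect_equal(g[2, 2, 1], 1)   # position of the 4
  expect_error(mc$netForward(mc$nnMaxPool(), array(0, c(5, 4, 1)), TRUE),
               "even")
})

test_that("SGD with momentum and weight decay matches hand arithmetic", {
  l <- mc$.newLayer("conv", W = matrix(1, 1, 1), b = 0, gW = matrix(0, 1, 1),
                    gb = 0, k = 1L, stride = 1L, pad = 0L, padMode = "zero",
                    cin = 1L)
  params <- list(list(env = l, w = "W", g = "gW"))
  opt <- mc$optSGD(params, lr = 0.1, momentum = 0.9, weightDecay = 0.01)
  ## step 1: g = 1 + 0.01*1 = 1.01; v = 1.01; w = 1 - 0.101 = 0.899
  l$gW <- matrix(1, 1, 1)
  mc$optStep(opt)
  expect_equal(l$W[1, 1], 1 - 0.1 * 1.01)
  ## step 2: g = 1 + 0.01*0.899; v = 0.9*1.01 + g; w -= 0.1*v
  g2 <- 1 + 0.01 * 0.899
  v2 <- 0.9 * 1.01 + g2
  w2 <- 0.899 - 0.1 * v2
  l$gW <- matrix(1, 1, 1)
  mc$optStep(opt)
  expect_equal(l$W[1, 1], w2, tolerance = 1e-12)
})

test_that("Adam's first step moves by lr regardless of gradient scale", {
  for (gval in c(0.001, 5)) {
    l <- mc$.newLayer("conv", W = matrix(2, 1, 1), b = 0,
                      gW = matrix(gval, 1, 1), gb = 0, k = 1L, stride = 1L,
                      pad = 0L, padMode = "zero", cin = 1L)
    opt <- mc$optAdam(list(list(env = l, w = "W", g = "gW")), lr = 0.01)
    mc$optStep(opt)
    ## bias-corrected first step: lr * g / (|g| + eps)
    expect_equal(l$W[1, 1], 2 - 0.01 * gval / (abs(gval) + 1e-8),
                 tolerance = 1e-9)
  }
})
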