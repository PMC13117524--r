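# Minimal dense/convolutional network engine used by the model builders.
#
# Activations flow as 4-D arrays [h, w, batch, channel] through the spatial
# layers and as [batch, feature] matrices after flatten / global pooling.
# Convolutions are 3x3, stride 1, zero same-padding, computed by im2col +
# BLAS GEMM; pointwise (1x1) and depthwise (3x3) variants support the
# depthwise-separable backbone. Training is Adam on softmax cross-entropy.
# Everything here is deterministic given the R RNG state and a fixed BLAS.

.heInit <- function(nOut, nIn, fanIn) {
  matrix(stats::rnorm(nIn * nOut, sd = sqrt(2 / fanIn)), nIn, nOut)
}

.layerConv <- function(inC, outC) {
  list(type = "conv", W = .heInit(outC, 9L * inC, 9L * inC),
       b = numeric(outC), trainable = TRUE)
}

.layerPwConv <- function(inC, outC) {
  list(type = "pwconv", W = .heInit(outC, inC, inC), trainable = TRUE)
}

.layerDwConv <- function(C) {
  list(type = "dwconv", W = matrix(stats::rnorm(9L * C, sd = sqrt(2 / 9)), 9L, C),
       trainable = TRUE)
}

.layerBN <- function(C) {
  list(type = "bn", gamma = rep(1, C), beta = numeric(C),
       rm = numeric(C), rv = rep(1, C), momentum = 0.9, eps = 1e-5,
       trainable = TRUE)
}

.layerReLU <- function() list(type = "relu")
.layerPool <- function() list(type = "pool")
.layerFlatten <- function() list(type = "flatten")
.layerGAP <- function() list(type = "gap")

.layerDense <- function(inD, outD) {
  list(type = "dense", W = .heInit(outD, inD, inD), b = numeric(outD),
       l2 = 0, trainable = TRUE)
}

# ---- forward passes ----------------------------------------------------

.padZero <- function(x) {
  d <- dim(x)
  Ap <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  Ap[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  Ap
}

# Column j of each per-channel block holds the (di, dj) offset; blocks are
# channel-major, i.e. column (ch - 1) * 9 + j.
.im2col3 <- function(Ap, h, w, n, cIn) {
  col <- matrix(0, h * w * n, 9L * cIn)
  chCols <- 9L * (seq_len(cIn) - 1L)
  j <- 0L
  for (dj in 0:2) for (di in 0:2) {
    j <- j + 1L
    blk <- Ap[di + seq_len(h), dj + seq_len(w), , , drop = FALSE]
    dim(blk) <- c(h * w * n, cIn)
    col[, j + chCols] <- blk
  }
  col
}

.fwdConv <- function(layer, x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; n <- d[3]; cIn <- d[4]
  col <- .im2col3(.padZero(x), h, w, n, cIn)
  Y <- col %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  dim(Y) <- c(h, w, n, ncol(layer$W))
  list(out = Y, cache = list(col = col, dims = d))
}

.bwdConv <- function(layer, cache, dout) {
  d <- cache$dims
  h <- d[1]; w <- d[2]; n <- d[3]; cIn <- d[4]
  f <- ncol(layer$W)
  dY <- dout; dim(dY) <- c(h * w * n, f)
  dW <- crossprod(cache$col, dY)
  db <- colSums(dY)
  dcol <- tcrossprod(dY, layer$W)
  dAp <- array(0, c(h + 2L, w + 2L, n, cIn))
  chCols <- 9L * (seq_len(cIn) - 1L)
  j <- 0L
  for (dj in 0:2) for (di in 0:2) {
    j <- j + 1L
    ri <- di + seq_len(h); ci <- dj + seq_len(w)
    dAp[ri, ci, , ] <- dAp[ri, ci, , ] +
      array(dcol[, j + chCols], c(h, w, n, cIn))
  }
  list(dx = dAp[2:(h + 1L), 2:(w + 1L), , , drop = FALSE],
       grads = list(W = dW, b = db))
}

.fwdPwConv <- function(layer, x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  Y <- xm %*% layer$W
  dim(Y) <- c(d[1], d[2], d[3], ncol(layer$W))
  list(out = Y, cache = list(xm = xm, dims = d))
}

.bwdPwConv <- function(layer, cache, dout) {
  d <- cache$dims
  dY <- dout; dim(dY) <- c(d[1] * d[2] * d[3], ncol(layer$W))
  dW <- crossprod(cache$xm, dY)
  dx <- tcrossprod(dY, layer$W)
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW))
}

.fwdDwConv <- function(layer, x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  Ap <- .padZero(x)
  Y <- array(0, d)
  j <- 0L
  for (dj in 0:2) for (di in 0:2) {
    j <- j + 1L
    blk <- Ap[di + seq_len(h), dj + seq_len(w), , , drop = FALSE]
    Y <- Y + blk * rep(layer$W[j, ], each = h * w * d[3])
  }
  list(out = Y, cache = list(Ap = Ap, dims = d))
}

.bwdDwConv <- function(layer, cache, dout) {
  d <- cache$dims
  h <- d[1]; w <- d[2]; n <- d[3]; C <- d[4]
  dW <- matrix(0, 9L, C)
  dAp <- array(0, dim(cache$Ap))
  j <- 0L
  for (dj in 0:2) for (di in 0:2) {
    j <- j + 1L
    ri <- di + seq_len(h); ci <- dj + seq_len(w)
    blk <- cache$Ap[ri, ci, , , drop = FALSE]
    pr <- blk * dout
    dim(pr) <- c(h * w * n, C)
    dW[j, ] <- colSums(pr)
    dAp[ri, ci, , ] <- dAp[ri, ci, , ] + dout * rep(layer$W[j, ], each = h * w * n)
  }
  list(dx = dAp[2:(h + 1L), 2:(w + 1L), , , drop = FALSE],
       grads = list(W = dW))
}

.fwdBN <- function(layer, x, training) {
  d <- dim(x)
  N <- prod(d[1:3])
  xm <- x; dim(xm) <- c(N, d[4])
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = N)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + layer$eps)
    xhat <- xc * rep(invstd, each = N)
    layer$rm <- layer$momentum * layer$rm + (1 - layer$momentum) * mu
    layer$rv <- layer$momentum * layer$rv + (1 - layer$momentum) * v
  } else {
    invstd <- 1 / sqrt(layer$rv + layer$eps)
    xhat <- (xm - rep(layer$rm, each = N)) * rep(invstd, each = N)
  }
  y <- xhat * rep(layer$gamma, each = N) + rep(layer$beta, each = N)
  dim(y) <- d
  list(out = y, cache = list(xhat = xhat, invstd = invstd, dims = d),
       layer = layer)
}

.bwdBN <- function(layer, cache, dout) {
  d <- cache$dims
  N <- prod(d[1:3])
  dym <- dout; dim(dym) <- c(N, d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(layer$gamma, each = N)
  t1 <- colSums(dxhat) / N
  t2 <- colSums(dxhat * xhat) / N
  dxm <- (dxhat - rep(t1, each = N) - xhat * rep(t2, each = N)) *
    rep(cache$invstd, each = N)
  dim(dxm) <- d
  list(dx = dxm, grads = list(gamma = dgamma, beta = dbeta))
}

.fwdReLU <- function(layer, x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

.bwdReLU <- function(layer, cache, dout) list(dx = dout * cache, grads = NULL)

.fwdPool <- function(layer, x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  x <- x[seq_len(2L * h2), seq_len(2L * w2), , , drop = FALSE]
  ro <- seq(1L, 2L * h2, 2L); co <- seq(1L, 2L * w2, 2L)
  a <- list(x[ro, co, , , drop = FALSE], x[ro + 1L, co, , , drop = FALSE],
            x[ro, co + 1L, , , drop = FALSE], x[ro + 1L, co + 1L, , , drop = FALSE])
  Y <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  rem <- array(TRUE, dim(Y))
  masks <- vector("list", 4L)
  for (k in 1:4) {                      # ties routed to the first window cell
    masks[[k]] <- (a[[k]] == Y) & rem
    rem <- rem & !masks[[k]]
  }
  list(out = Y, cache = list(masks = masks, dims = d, h2 = h2, w2 = w2))
}

.bwdPool <- function(layer, cache, dout) {
  d <- cache$dims
  dx <- array(0, d)
  ro <- seq(1L, 2L * cache$h2, 2L); co <- seq(1L, 2L * cache$w2, 2L)
  dx[ro, co, , ] <- dout * cache$masks[[1]]
  dx[ro + 1L, co, , ] <- dout * cache$masks[[2]]
  dx[ro, co + 1L, , ] <- dout * cache$masks[[3]]
  dx[ro + 1L, co + 1L, , ] <- dout * cache$masks[[4]]
  list(dx = dx, grads = NULL)
}

.fwdFlatten <- function(layer, x) {
  d <- dim(x)
  ap <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(ap) <- c(d[1] * d[2] * d[4], d[3])
  list(out = t(ap), cache = d)
}

.bwdFlatten <- function(layer, cache, dout) {
  d <- cache
  dx <- t(dout)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1L, 2L, 4L, 3L)), grads = NULL)
}

.fwdGAP <- function(layer, x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  list(out = matrix(colMeans(xm), d[3], d[4]), cache = d)
}

.bwdGAP <- function(layer, cache, dout) {
  d <- cache
  hw <- d[1] * d[2]
  dx <- array(rep(as.vector(dout) / hw, each = hw), d)
  list(dx = dx, grads = NULL)
}

.fwdDense <- function(layer, x) {
  Y <- x %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  list(out = Y, cache = x)
}

.bwdDense <- function(layer, cache, dout) {
  dW <- crossprod(cache, dout)
  if (layer$l2 > 0) dW <- dW + layer$l2 * layer$W
  list(dx = tcrossprod(dout, layer$W),
       grads = list(W = dW, b = colSums(dout)))
}

# ---- engine ------------------------------------------------------------

.nnForward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
                conv = .fwdConv(l, x),
                pwconv = .fwdPwConv(l, x),
                dwconv = .fwdDwConv(l, x),
                bn = .fwdBN(l, x, training),
                relu = .fwdReLU(l, x),
                pool = .fwdPool(l, x),
                flatten = .fwdFlatten(l, x),
                gap = .fwdGAP(l, x),
                dense = .fwdDense(l, x),
                stop("unknown layer type: ", l$type))
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$layer)) layers[[i]] <- r$layer  # BN running stats
  }
  list(out = x, caches = caches, layers = layers)
}

.nnBackward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
                conv = .bwdConv(l, caches[[i]], dout),
                pwconv = .bwdPwConv(l, caches[[i]], dout),
                dwconv = .bwdDwConv(l, caches[[i]], dout),
                bn = .bwdBN(l, caches[[i]], dout),
                relu = .bwdReLU(l, caches[[i]], dout),
                pool = .bwdPool(l, caches[[i]], dout),
                flatten = .bwdFlatten(l, caches[[i]], dout),
                gap = .bwdGAP(l, caches[[i]], dout),
                dense = .bwdDense(l, caches[[i]], dout))
    if (!is.null(r$grads)) grads[[i]] <- r$grads
    dout <- r$dx
  }
  grads
}

.softmaxProbs <- function(logits) {
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

# Sparse categorical cross-entropy; y is an integer vector in 1..K.
.ceLossGrad <- function(logits, y) {
  n <- nrow(logits)
  p <- .softmaxProbs(logits)
  ll <- p[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(ll, 1e-12)))
  dl <- p
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = p, dlogits = dl / n)
}

.adamInit <- function(layers) {
  lapply(layers, function(l) {
    nms <- intersect(c("W", "b", "gamma", "beta"), names(l))
    st <- lapply(nms, function(p) list(m = 0 * l[[p]], v = 0 * l[[p]]))
    names(st) <- nms
    st
  })
}

.adamStep <- function(layers, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g) || !isTRUE(layers[[i]]$trainable)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

.layerParamCount <- function(l, trainableOnly = FALSE, includeRunningStats = FALSE) {
  if (trainableOnly && !isTRUE(l$trainable) && !is.null(l$trainable)) return(0L)
  n <- switch(l$type,
              conv = length(l$W) + length(l$b),
              pwconv = length(l$W),
              dwconv = length(l$W),
              dense = length(l$W) + length(l$b),
              bn = length(l$gamma) + length(l$beta) +
                if (includeRunningStats) length(l$rm) + length(l$rv) else 0L,
              0L)
  as.integer(n)
}
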