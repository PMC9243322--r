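# Minimal convolutional network engine.
#
# All spatial tensors are H x W x C x N arrays (column-major). A network is
# a list of layer descriptors plus a parallel list of parameter lists; the
# forward pass returns per-layer caches that the backward pass consumes.
# Convolution uses im2col patch matrices (compiled) against BLAS matmul.

initLayerParams <- function(layer) {
  switch(layer$type,
    conv = {
      fanIn <- layer$k^2 * layer$inC
      list(W = matrix(rnorm(fanIn * layer$outC, sd = sqrt(2 / fanIn)),
                      fanIn, layer$outC),
           b = numeric(layer$outC))
    },
    cbam = {
      C <- layer$channels
      Cr <- max(1L, C %/% layer$reduction)
      k <- layer$spatialKernel
      list(W1 = matrix(rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C),
           b1 = numeric(Cr),
           W2 = matrix(rnorm(C * Cr, sd = sqrt(2 / Cr)), C, Cr),
           b2 = numeric(C),
           convW = rnorm(k^2 * 2, sd = sqrt(2 / (k^2 * 2))),
           convb = 0)
    },
    gap = list(),
    bn = list(gamma = rep(1, layer$width), beta = numeric(layer$width),
              rmean = numeric(layer$width), rvar = rep(1, layer$width)),
    dense = list(W = matrix(rnorm(layer$inD * layer$outD,
                                  sd = sqrt(1 / layer$inD)),
                            layer$inD, layer$outD),
                 b = numeric(layer$outD)),
    stop("unknown layer type: ", layer$type)
  )
}

convOut <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

convForward <- function(x, p, layer) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- layer$k; s <- layer$stride; pad <- layer$pad
  OH <- convOut(H, k, s, pad); OW <- convOut(W, k, s, pad)
  col <- im2col_cpp(x, H, W, C, N, k, s, pad)
  out <- col %*% p$W
  out <- out + rep(p$b, each = nrow(out))
  mask <- NULL
  if (isTRUE(layer$relu)) {
    mask <- out > 0
    out <- out * mask
  }
  y <- aperm(array(out, c(OH, OW, N, layer$outC)), c(1, 2, 4, 3))
  list(out = y, cache = list(col = col, mask = mask, inDim = d,
                             OH = OH, OW = OW))
}

convBackward <- function(dout, p, layer, cache) {
  OH <- cache$OH; OW <- cache$OW
  N <- cache$inDim[4]
  dmat <- aperm(dout, c(1, 2, 4, 3))
  dim(dmat) <- c(OH * OW * N, layer$outC)
  if (!is.null(cache$mask)) dmat <- dmat * cache$mask
  dW <- crossprod(cache$col, dmat)
  db <- colSums(dmat)
  dcol <- dmat %*% t(p$W)
  d <- cache$inDim
  dx <- col2im_cpp(dcol, d[1], d[2], d[3], d[4], layer$k, layer$stride,
                   layer$pad)
  dim(dx) <- d
  list(dx = dx, dp = list(W = dW, b = db))
}

# Column-wise max with argmax over a matrix, per column.
colMaxWhich <- function(m) {
  idx <- max.col(t(m), ties.method = "first")
  list(max = m[cbind(idx, seq_len(ncol(m)))], idx = idx)
}

cbamForward <- function(x, p, layer) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  xm <- x; dim(xm) <- c(HW, C * N)

  # -- channel attention: shared MLP over avg- and max-pooled descriptors
  sAvg <- matrix(colMeans(xm), C, N)
  mx <- colMaxWhich(xm)
  sMax <- matrix(mx$max, C, N)
  a1A <- p$W1 %*% sAvg + p$b1; h1A <- a1A * (a1A > 0)
  a1M <- p$W1 %*% sMax + p$b1; h1M <- a1M * (a1M > 0)
  # shared MLP applied to each descriptor, branch outputs summed (bias
  # enters through both branches)
  zc <- p$W2 %*% h1A + p$W2 %*% h1M + 2 * p$b2
  ac <- sigmoid(zc)                               # C x N channel coefficients
  x1m <- xm * rep(as.vector(ac), each = HW)
  x1 <- x1m; dim(x1) <- d

  # -- spatial attention: conv over channelwise avg/max maps
  xp <- aperm(x1, c(1, 2, 4, 3))                  # H,W,N,C
  xpm <- xp; dim(xpm) <- c(HW * N, C)
  mAvg <- rowMeans(xpm)
  sm <- colMaxWhich(t(xpm))                       # per row of xpm
  mMax <- sm$max
  stack <- array(c(mAvg, mMax), c(H, W, N, 2))
  stack <- aperm(stack, c(1, 2, 4, 3))            # H,W,2,N
  k <- layer$spatialKernel
  pad <- (k - 1L) %/% 2L
  colS <- im2col_cpp(stack, H, W, 2L, N, k, 1L, pad)
  zs <- as.vector(colS %*% p$convW) + p$convb     # H*W*N logits
  as_ <- sigmoid(zs)                              # spatial coefficients
  y <- xp * as_                                   # recycles over C
  y <- aperm(y, c(1, 2, 4, 3))

  list(out = y,
       cache = list(inDim = d, xm = xm, sAvg = sAvg, sMax = sMax,
                    mxIdx = mx$idx, a1A = a1A, a1M = a1M, h1A = h1A,
                    h1M = h1M, ac = ac, x1 = x1, xp = xp, xpm = xpm,
                    smIdx = sm$idx, colS = colS, as_ = as_, pad = pad))
}

cbamBackward <- function(dout, p, layer, cache) {
  d <- cache$inDim
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  k <- layer$spatialKernel

  dyp <- aperm(dout, c(1, 2, 4, 3))               # H,W,N,C
  # y = xp * as_
  dxp <- dyp * cache$as_
  dypm <- dyp; dim(dypm) <- c(HW * N, C)
  xpm <- cache$xpm
  das <- rowSums(dypm * xpm)                      # H*W*N
  dzs <- das * cache$as_ * (1 - cache$as_)
  dconvW <- as.vector(crossprod(cache$colS, dzs))
  dconvb <- sum(dzs)
  dcolS <- tcrossprod(dzs, p$convW)               # (H*W*N) x (k*k*2)
  pad <- cache$pad
  dstack <- col2im_cpp(dcolS, H, W, 2L, N, k, 1L, pad)
  dim(dstack) <- c(H, W, 2, N)
  dstack <- aperm(dstack, c(1, 2, 4, 3))          # H,W,N,2
  dmAvg <- as.vector(dstack[, , , 1])
  dmMax <- as.vector(dstack[, , , 2])
  # avg map spreads evenly over channels; max map routes to argmax channel
  dxpm <- dxp; dim(dxpm) <- c(HW * N, C)
  dxpm <- dxpm + dmAvg / C
  idx <- cbind(seq_len(HW * N), cache$smIdx)
  dxpm[idx] <- dxpm[idx] + dmMax
  dx1 <- dxpm; dim(dx1) <- c(H, W, N, C)
  dx1 <- aperm(dx1, c(1, 2, 4, 3))                # H,W,C,N
  dx1m <- dx1; dim(dx1m) <- c(HW, C * N)

  # x1 = x * ac (channel broadcast)
  acv <- as.vector(cache$ac)
  dxm <- dx1m * rep(acv, each = HW)
  dac <- matrix(colSums(dx1m * cache$xm), C, N)
  dzc <- dac * cache$ac * (1 - cache$ac)          # C x N
  # zc = W2 h1A + W2 h1M + 2 b2 (bias enters both branches)
  dh1A <- crossprod(p$W2, dzc) * (cache$a1A > 0)
  dh1M <- crossprod(p$W2, dzc) * (cache$a1M > 0)
  dW2 <- tcrossprod(dzc, cache$h1A) + tcrossprod(dzc, cache$h1M)
  db2 <- 2 * rowSums(dzc)
  dW1 <- tcrossprod(dh1A, cache$sAvg) + tcrossprod(dh1M, cache$sMax)
  db1 <- rowSums(dh1A + dh1M)
  dsAvg <- crossprod(p$W1, dh1A)                  # C x N
  dsMax <- crossprod(p$W1, dh1M)
  dxm <- dxm + rep(as.vector(dsAvg), each = HW) / HW
  midx <- cbind(cache$mxIdx, seq_len(C * N))
  dsMaxV <- as.vector(dsMax)
  # scatter max-pool gradient back to the arg-max spatial position
  flat <- (seq_len(C * N) - 1L) * HW + cache$mxIdx
  dxm[flat] <- dxm[flat] + dsMaxV
  dx <- dxm; dim(dx) <- d

  list(dx = dx, dp = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                          convW = dconvW, convb = dconvb))
}

gapForward <- function(x, layer = list()) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
  e <- t(matrix(colMeans(m), d[3], d[4]))         # N x C
  list(out = e, cache = list(d = d))
}

gapBackward <- function(dout, cache) {
  d <- cache$d
  HW <- d[1] * d[2]
  v <- as.vector(t(dout)) / HW                    # C*N
  dx <- matrix(rep(v, each = HW), HW)
  dim(dx) <- d
  list(dx = dx, dp = list())
}

# Feature-wise batch normalization of an N x C embedding. Training uses
# batch statistics and reports running-average updates (applied by the
# trainer, never by the optimizer); inference uses the running
# statistics.
bnForward <- function(x, p, layer, train = FALSE) {
  eps <- 1e-5
  if (train && nrow(x) > 1L) {
    mu <- colMeans(x)
    va <- colMeans(x^2) - mu^2
    va[va < 0] <- 0
    mom <- layer$momentum %||% 0.1
    upd <- list(rmean = (1 - mom) * p$rmean + mom * mu,
                rvar = (1 - mom) * p$rvar + mom * va)
  } else {
    mu <- p$rmean; va <- p$rvar; upd <- NULL
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(x, 2L, mu), 2L, ivar, "*")
  out <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(out = out, cache = list(xhat = xhat, ivar = ivar, train = train),
       upd = upd)
}

bnBackward <- function(dout, p, cache) {
  xhat <- cache$xhat; ivar <- cache$ivar
  N <- nrow(dout)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, p$gamma, "*")
  if (cache$train && N > 1L) {
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * xhat)
    dx <- sweep(dxhat * N, 2L, t1) - sweep(xhat, 2L, t2, "*")
    dx <- sweep(dx, 2L, ivar / N, "*")
  } else {
    dx <- sweep(dxhat, 2L, ivar, "*")
  }
  list(dx = dx, dp = list(gamma = dgamma, beta = dbeta, rmean = NULL,
                          rvar = NULL))
}

denseForward <- function(x, p) {
  out <- x %*% p$W
  out <- out + rep(p$b, each = nrow(out))
  list(out = out, cache = x)
}

denseBackward <- function(dout, p, cache) {
  list(dx = dout %*% t(p$W),
       dp = list(W = crossprod(cache, dout), b = colSums(dout)))
}

# Run a layer stack; returns final output plus per-layer caches and the
# indices of the post-CBAM feature map and pooled embedding when present.
nnForward <- function(layers, params, x, train = FALSE) {
  caches <- vector("list", length(layers))
  featureMap <- NULL; embedding <- NULL
  bnUpdates <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = convForward(x, params[[i]], l),
      cbam = cbamForward(x, params[[i]], l),
      gap = gapForward(x, l),
      bn = bnForward(x, params[[i]], l, train),
      dense = denseForward(x, params[[i]]))
    x <- r$out
    caches[[i]] <- r$cache
    if (l$type == "cbam") featureMap <- x
    if (l$type %in% c("gap", "bn")) embedding <- x
    if (!is.null(r$upd)) bnUpdates[[as.character(i)]] <- r$upd
  }
  list(out = x, caches = caches, featureMap = featureMap,
       embedding = embedding, bnUpdates = bnUpdates)
}

# Write running-statistic updates reported by nnForward back into a
# parameter list (buffers are trainer state, not optimizer state).
applyBnUpdates <- function(params, bnUpdates) {
  for (key in names(bnUpdates)) {
    i <- as.integer(key)
    params[[i]]$rmean <- bnUpdates[[key]]$rmean
    params[[i]]$rvar <- bnUpdates[[key]]$rvar
  }
  params
}

# Backpropagate dout through the stack; returns per-layer parameter grads
# and the gradient w.r.t. the input. `upto` stops early (gradients for
# layers < upto are skipped), used when the trunk is frozen.
nnBackward <- function(layers, params, caches, dout, upto = 1L) {
  n <- length(layers)
  dparams <- vector("list", n)
  for (i in rev(seq_len(n))) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = convBackward(dout, params[[i]], l, caches[[i]]),
      cbam = cbamBackward(dout, params[[i]], l, caches[[i]]),
      gap = gapBackward(dout, caches[[i]]),
      bn = bnBackward(dout, params[[i]], caches[[i]]),
      dense = denseBackward(dout, params[[i]], caches[[i]]))
    dparams[[i]] <- r$dp
    dout <- r$dx
    if (i == upto) break
  }
  list(dparams = dparams, dx = dout)
}

# Set each bn layer's running statistics to the exact feature moments of
# a reference batch (typically the full training set), so inference-mode
# normalization matches the final state of the trunk.
calibrateBnStats <- function(layers, params, x) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "bn") {
      mu <- colMeans(x)
      va <- colMeans(x^2) - mu^2
      va[va < 0] <- 0
      params[[i]]$rmean <- mu
      params[[i]]$rvar <- va
    }
    r <- switch(l$type,
      conv = convForward(x, params[[i]], l),
      cbam = cbamForward(x, params[[i]], l),
      gap = gapForward(x, l),
      bn = bnForward(x, params[[i]], l, train = FALSE),
      dense = denseForward(x, params[[i]]))
    x <- r$out
  }
  params
}

# ---- optimizers ------------------------------------------------------------

zerosLike <- function(p) lapply(p, function(x) {
  if (is.list(x)) zerosLike(x) else x * 0
})

adamInit <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(kind = "adam", lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L, m = zerosLike(params), v = zerosLike(params))
}

sgdInit <- function(params, lr = 1e-2) list(kind = "sgd", lr = lr)

# Apply one optimizer step. `grads` mirrors `params`; NULL entries (at any
# nesting level) are skipped, leaving those parameters bit-identical —
# this implements parameter freezing.
optimStep <- function(opt, params, grads) {
  # gradient lists mirror the parameter lists; when both carry names the
  # lookup is by name, otherwise positional
  gradKey <- function(p, g, i) {
    if (!is.null(names(p)) && !is.null(names(g))) names(p)[i] else i
  }
  if (opt$kind == "sgd") {
    step <- function(p, g) {
      for (i in seq_along(p)) {
        k <- gradKey(p, g, i)
        gv <- tryCatch(g[[k]], error = function(e) NULL)
        if (is.null(gv)) next
        if (is.list(p[[i]])) p[[i]] <- step(p[[i]], gv)
        else p[[i]] <- p[[i]] - opt$lr * gv
      }
      p
    }
    return(list(opt = opt, params = step(params, grads)))
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  step <- function(p, g, m, v) {
    for (i in seq_along(p)) {
      k <- gradKey(p, g, i)
      gv <- tryCatch(g[[k]], error = function(e) NULL)
      if (is.null(gv)) next
      if (is.list(p[[i]])) {
        r <- step(p[[i]], gv, m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      } else {
        m[[i]] <- opt$beta1 * m[[i]] + (1 - opt$beta1) * gv
        v[[i]] <- opt$beta2 * v[[i]] + (1 - opt$beta2) * gv^2
        p[[i]] <- p[[i]] - opt$lr * (m[[i]] / bc1) /
          (sqrt(v[[i]] / bc2) + opt$eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  r <- step(params, grads, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(opt = opt, params = r$p)
}

softmaxBackward <- function(probs, dprobs) {
  probs * (dprobs - rowSums(dprobs * probs))
}
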