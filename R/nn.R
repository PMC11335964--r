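## Minimal 1-D convolutional network engine.
##
## The classifier convolves along the time axis with the EEG channels as
## input feature maps: BatchNorm -> 4 x (Conv -> GELU -> MaxPool) ->
## BatchNorm -> flatten -> 3 hidden dense (ReLU) -> softmax output.
## Everything (forward, backprop, Adam, input gradients for attribution)
## is expressed as BLAS matrix products on an im2col unrolling, so
## training runs at practical speed on a single CPU.
##
## Batch layout: arrays [channels, times, batch] through the conv stage,
## matrices [features, batch] through the dense stage.

.geluF <- function(x) x * pnorm(x)
.geluG <- function(x) pnorm(x) + x * dnorm(x)

.glorotNormal <- function(nr, nc, fanIn, fanOut) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / (fanIn + fanOut))), nr, nc)
}
.glorotUniform <- function(nr, nc, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

.layerParamNames <- function(layer) {
  switch(layer$type,
         bn = c("gamma", "beta"),
         conv = c("W", "b"),
         dense = c("W", "b"),
         character(0))
}

## ---- forward ---------------------------------------------------------

## Unroll a [C, T, B] array into the [C*K, T*B] im2col matrix of a
## stride-1, zero-padded 1-D convolution.  Done as one indexed gather:
## element (r, col) with r = c + C*(k-1) and col = t + T*(b-1) sits at
## padded-array index r + C*(t-1) + C*Tp*(b-1).
.im2colCache <- new.env(parent = emptyenv())

.im2colIndex <- function(C, K, T, B, padL, padR) {
  key <- paste(C, K, T, B, padL, padR, sep = ".")
  idx <- .im2colCache[[key]]
  if (is.null(idx)) {
    Tp <- T + padL + padR
    colOff <- C * (rep(0:(T - 1L), times = B) +
                     Tp * rep(0:(B - 1L), each = T))
    idx <- rep(colOff, each = C * K) + seq_len(C * K)
    if (length(idx) <= 5e7) .im2colCache[[key]] <- idx
  }
  idx
}

.im2col <- function(X, K, padL, padR) {
  d <- dim(X); C <- d[1L]; T <- d[2L]; B <- d[3L]
  Xp <- array(0, c(C, T + padL + padR, B))
  Xp[, padL + seq_len(T), ] <- X
  M <- Xp[.im2colIndex(C, K, T, B, padL, padR)]
  dim(M) <- c(C * K, T * B)
  M
}

## Gradient of the convolution w.r.t. its input, written as the
## correlation of dY with the kernel flipped along time (so it reuses the
## im2col + GEMM path instead of a scatter-add).
.convBackwardInput <- function(W, dY, C, K, padL, padR) {
  F <- nrow(W)
  Wk <- array(W, c(F, C, K))
  W2 <- aperm(Wk[, , K:1, drop = FALSE], c(2L, 1L, 3L))
  dim(W2) <- c(C, F * K)
  W2 %*% .im2col(dY, K, padR, padL)
}

## Forward pass.  training=TRUE uses batch statistics in the BN layers and
## returns updated running moments; keepCache retains the intermediates
## needed by the backward pass.
.nnForward <- function(layers, X, training = FALSE, keepCache = FALSE) {
  caches <- if (keepCache) vector("list", length(layers)) else NULL
  for (li in seq_along(layers)) {
    layer <- layers[[li]]
    cache <- NULL
    if (layer$type == "bn") {
      d <- dim(X); C <- d[1L]
      M <- matrix(X, C)
      if (training) {
        m <- rowMeans(M)
        v <- rowMeans(M * M) - m^2
        mom <- layer$momentum
        layers[[li]]$runMean <- mom * layer$runMean + (1 - mom) * m
        layers[[li]]$runVar <- mom * layer$runVar + (1 - mom) * v
      } else {
        m <- layer$runMean
        v <- layer$runVar
      }
      istd <- 1 / sqrt(v + layer$eps)
      xhat <- (M - m) * istd
      Y <- layer$gamma * xhat + layer$beta
      if (keepCache) cache <- list(xhat = xhat, istd = istd, dims = d)
      X <- array(Y, d)
    } else if (layer$type == "conv") {
      d <- dim(X); C <- d[1L]; T <- d[2L]; B <- d[3L]
      M <- .im2col(X, layer$K, layer$padL, layer$padR)
      Y <- layer$W %*% M + layer$b
      if (keepCache) cache <- list(M = M, dims = d)
      X <- array(Y, c(nrow(layer$W), T, B))
    } else if (layer$type == "gelu") {
      if (keepCache) cache <- list(X = X)
      X <- .geluF(X)
    } else if (layer$type == "pool") {
      d <- dim(X); F <- d[1L]; T <- d[2L]; B <- d[3L]
      p <- layer$size
      To <- T %/% p
      best <- X[, seq(1L, by = p, length.out = To), , drop = FALSE]
      arg <- array(1L, c(F, To, B))
      if (p > 1L) for (k in 2L:p) {
        cand <- X[, seq(k, by = p, length.out = To), , drop = FALSE]
        upd <- cand > best
        best[upd] <- cand[upd]
        arg[upd] <- k
      }
      if (keepCache) cache <- list(arg = arg, Tin = T, dims = d)
      X <- best
    } else if (layer$type == "flatten") {
      d <- dim(X)
      if (keepCache) cache <- list(dims = d)
      X <- matrix(X, d[1L] * d[2L], d[3L])
    } else if (layer$type == "dense") {
      A <- X
      Z <- layer$W %*% A + layer$b
      Y <- switch(layer$activation,
                  relu = pmax(Z, 0),
                  linear = Z,
                  softmax = {
                    E <- exp(sweep(Z, 2L, apply(Z, 2L, max)))
                    sweep(E, 2L, colSums(E), "/")
                  })
      if (keepCache) cache <- list(A = A, Z = Z, Y = Y)
      X <- Y
    } else stop("unknown layer type: ", layer$type)
    if (keepCache) caches[[li]] <- cache
  }
  list(out = X, caches = caches, layers = layers)
}

## Backward pass.  `dTop` is the gradient at the network output: for
## training it is the gradient at the softmax *pre-activation* (pass
## topIsPreact = TRUE, the fused softmax + cross-entropy shortcut); for
## attribution it is the gradient of a scalar in the output probabilities.
## Returns parameter gradients (if wanted) and the input gradient.
.nnBackward <- function(layers, caches, dTop, training = FALSE,
                        paramGrads = TRUE, inputGrad = FALSE,
                        topIsPreact = FALSE, l2 = 0) {
  grads <- if (paramGrads) vector("list", length(layers)) else NULL
  dX <- dTop
  for (li in rev(seq_along(layers))) {
    layer <- layers[[li]]
    cache <- caches[[li]]
    if (layer$type == "dense") {
      if (layer$activation == "softmax" && !topIsPreact) {
        P <- cache$Y
        dZ <- P * sweep(dX, 2L, colSums(dX * P))
      } else if (layer$activation == "softmax" && topIsPreact) {
        dZ <- dX
      } else if (layer$activation == "relu") {
        dZ <- dX * (cache$Z > 0)
      } else dZ <- dX
      if (paramGrads) {
        gW <- tcrossprod(dZ, cache$A)
        grads[[li]] <- list(W = gW, b = rowSums(dZ))
      }
      if (inputGrad || li > 1L) dX <- crossprod(layer$W, dZ)
    } else if (layer$type == "flatten") {
      dX <- array(dX, cache$dims)
    } else if (layer$type == "pool") {
      d <- cache$dims; F <- d[1L]; T <- d[2L]; B <- d[3L]
      p <- layer$size
      To <- dim(cache$arg)[2L]
      dIn <- array(0, d)
      f <- rep.int(seq_len(F), To * B)
      to <- rep.int(rep(seq_len(To), each = F), B)
      bb <- rep(seq_len(B), each = F * To)
      tFull <- (to - 1L) * p + as.vector(cache$arg)
      dIn[f + F * (tFull - 1L) + F * T * (bb - 1L)] <- as.vector(dX)
      dX <- dIn
    } else if (layer$type == "gelu") {
      dX <- dX * .geluG(cache$X)
    } else if (layer$type == "conv") {
      d <- cache$dims; C <- d[1L]; T <- d[2L]; B <- d[3L]
      dYmat <- matrix(dX, nrow(layer$W))
      if (paramGrads) {
        gW <- tcrossprod(dYmat, cache$M)
        if (l2 > 0) gW <- gW + 2 * l2 * layer$W
        grads[[li]] <- list(W = gW, b = rowSums(dYmat))
      }
      if (inputGrad || li > 1L) {
        dYarr <- dX
        if (!is.array(dYarr) || length(dim(dYarr)) != 3L)
          dYarr <- array(dX, c(nrow(layer$W), T, B))
        dX <- array(.convBackwardInput(layer$W, dYarr, C, layer$K,
                                       layer$padL, layer$padR),
                    c(C, T, B))
      }
    } else if (layer$type == "bn") {
      d <- cache$dims; C <- d[1L]
      dY <- matrix(dX, C)
      if (paramGrads)
        grads[[li]] <- list(gamma = rowSums(dY * cache$xhat),
                            beta = rowSums(dY))
      if (inputGrad || li > 1L) {
        if (training) {
          N <- ncol(dY)
          dxhat <- dY * layer$gamma
          dM <- (cache$istd / N) *
            (N * dxhat - rowSums(dxhat) -
               cache$xhat * rowSums(dxhat * cache$xhat))
        } else {
          dM <- dY * (layer$gamma * cache$istd)
        }
        dX <- array(dM, d)
      }
    }
  }
  list(grads = grads, dInput = dX)
}

## ---- Adam ------------------------------------------------------------

.adamInit <- function(layers) {
  lapply(layers, function(layer) {
    nm <- .layerParamNames(layer)
    if (!length(nm)) return(NULL)
    st <- list()
    for (p in nm) {
      z <- layer[[p]] * 0
      st[[p]] <- list(m = z, v = z)
    }
    st
  })
}

.adamStep <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[li]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      layers[[li]][[p]] <- layers[[li]][[p]] -
        lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
      state[[li]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

## ---- batched inference helpers ---------------------------------------

.inferChunk <- function(nChannels, kernel, nTimes, target = 4e7) {
  max(1L, min(256L, as.integer(target / (nChannels * kernel * nTimes))))
}

## Forward in inference mode over a possibly large batch, chunked to bound
## the im2col workspace.
.nnPredict <- function(model, X) {
  d <- dim(X); B <- d[3L]
  chunk <- .inferChunk(d[1L], model$spec$kernelSize, d[2L])
  out <- matrix(0, model$spec$nClasses, B)
  i <- 1L
  while (i <= B) {
    j <- min(B, i + chunk - 1L)
    out[, i:j] <- .nnForward(model$layers, X[, , i:j, drop = FALSE],
                             training = FALSE)$out
    i <- j + 1L
  }
  out
}

## ---- training --------------------------------------------------------

.crossEntropy <- function(P, yIdx) {
  -mean(log(pmax(P[cbind(yIdx, seq_along(yIdx))], 1e-12)))
}

.l2Penalty <- function(layers, l2) {
  if (l2 <= 0) return(0)
  s <- 0
  for (layer in layers)
    if (layer$type == "conv") s <- s + sum(layer$W^2)
  l2 * s
}

## Fit one model on (Xtr, ytr) with validation-based checkpointing:
## the returned weights are those of the epoch with the best validation
## accuracy, while early stopping monitors validation loss with the
## configured patience.
.fitModel <- function(model, Xtr, ytr, Xval, yval, cfg) {
  layers <- model$layers
  state <- .adamInit(layers)
  nTr <- length(ytr)
  lr <- model$spec$learningRate
  l2 <- model$spec$l2
  step <- 0L
  bestAcc <- -Inf; bestLayers <- layers
  bestLoss <- Inf; bestLossEpoch <- 0L
  hist <- NULL
  for (epoch in seq_len(cfg$maxEpochs)) {
    ord <- sample.int(nTr)
    trLoss <- 0; nb <- 0L
    for (start in seq(1L, nTr, by = cfg$batchSize)) {
      idx <- ord[start:min(nTr, start + cfg$batchSize - 1L)]
      Xb <- Xtr[, , idx, drop = FALSE]
      yb <- ytr[idx]
      fw <- .nnForward(layers, Xb, training = TRUE, keepCache = TRUE)
      layers <- fw$layers
      P <- fw$out
      loss <- .crossEntropy(P, yb) + .l2Penalty(layers, l2)
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      Y1 <- matrix(0, nrow(P), ncol(P))
      Y1[cbind(yb, seq_along(yb))] <- 1
      dZ <- (P - Y1) / length(yb)
      bw <- .nnBackward(layers, fw$caches, dZ, training = TRUE,
                        topIsPreact = TRUE, l2 = l2)
      step <- step + 1L
      upd <- .adamStep(layers, bw$grads, state, lr, step)
      layers <- upd$layers; state <- upd$state
      trLoss <- trLoss + loss; nb <- nb + 1L
    }
    Pval <- .nnPredict(list(spec = model$spec, layers = layers), Xval)
    valLoss <- .crossEntropy(Pval, yval)
    valAcc <- mean(max.col(t(Pval)) == yval)
    hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = trLoss / nb,
                                   valLoss = valLoss, valAcc = valAcc))
    if (valAcc > bestAcc) {
      bestAcc <- valAcc
      bestLayers <- layers
    }
    if (valLoss < bestLoss) {
      bestLoss <- valLoss
      bestLossEpoch <- epoch
    }
    if (epoch - bestLossEpoch >= cfg$earlyStopPatience) break
  }
  model$layers <- bestLayers
  list(model = model, history = hist, bestValAcc = bestAcc)
}
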