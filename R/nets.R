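# Neural model families built on the autodiff tape (autograd.R): parameter
# initialization, forward passes, and a shared Adam training loop with
# early stopping on validation loss.

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

netInitParams <- function(family, inputDim, hyper) {
  switch(family,
    mlp = {
      h <- hyper$hidden %||% c(64L, 32L)
      p <- list()
      dims <- c(inputDim, h, 1L)
      for (i in seq_len(length(dims) - 1L)) {
        p[[paste0("W", i)]] <- glorot(dims[i], dims[i + 1L])
        p[[paste0("b", i)]] <- numeric(dims[i + 1L])
      }
      p
    },
    gru = {
      h <- hyper$width %||% 64L
      f <- inputDim$nFeat
      list(Wz = glorot(f, h), Uz = glorot(h, h), bz = numeric(h),
           Wr = glorot(f, h), Ur = glorot(h, h), br = numeric(h),
           Wh = glorot(f, h), Uh = glorot(h, h), bh = numeric(h),
           Wo = glorot(h, 1L), bo = numeric(1L))
    },
    transformer = {
      d <- hyper$dModel %||% 32L
      ff <- hyper$dFF %||% 64L
      nb <- hyper$nBlocks %||% 2L
      p <- list(Win = glorot(inputDim$nFeat, d), bin = numeric(d))
      for (i in seq_len(nb)) {
        pre <- paste0("blk", i, ".")
        p[[paste0(pre, "Wq")]] <- glorot(d, d)
        p[[paste0(pre, "Wk")]] <- glorot(d, d)
        p[[paste0(pre, "Wv")]] <- glorot(d, d)
        p[[paste0(pre, "Wo")]] <- glorot(d, d)
        p[[paste0(pre, "bo")]] <- numeric(d)
        p[[paste0(pre, "g1")]] <- rep(1, d)
        p[[paste0(pre, "beta1")]] <- numeric(d)
        p[[paste0(pre, "g2")]] <- rep(1, d)
        p[[paste0(pre, "beta2")]] <- numeric(d)
        p[[paste0(pre, "Wf1")]] <- glorot(d, ff)
        p[[paste0(pre, "bf1")]] <- numeric(ff)
        p[[paste0(pre, "Wf2")]] <- glorot(ff, d)
        p[[paste0(pre, "bf2")]] <- numeric(d)
      }
      p$Wout <- glorot(d, 1L)
      p$bout <- numeric(1L)
      p
    },
    cnn1d = {
      ch <- hyper$filters %||% c(16L, 16L, 16L)
      ks <- hyper$kernels %||% c(7L, 5L, 3L)
      inC <- inputDim$nChan
      p <- list()
      for (i in seq_along(ch)) {
        p[[paste0("Wc", i)]] <- array(stats::rnorm(inC * ks[i] * ch[i],
                                                   sd = sqrt(2 / (inC * ks[i]))),
                                      c(inC, ks[i], ch[i]))
        p[[paste0("bc", i)]] <- numeric(ch[i])
        inC <- ch[i]
      }
      p$Wout <- glorot(inC, 1L)
      p$bout <- numeric(1L)
      p
    },
    stop("unknown neural family: ", family))
}

# sinusoidal positional encoding, T x d
posEncoding <- function(tLen, d) {
  pos <- seq_len(tLen) - 1
  i <- seq_len(d) - 1
  ang <- outer(pos, 1 / 10000^(2 * (i %/% 2) / d))
  pe <- ang
  pe[, i %% 2 == 0] <- sin(ang[, i %% 2 == 0])
  pe[, i %% 2 == 1] <- cos(ang[, i %% 2 == 1])
  pe
}

netForward <- function(family, tape, P, X, hyper) {
  switch(family,
    mlp = {
      nLayers <- length(P) / 2L
      a <- agNode(tape, X)
      for (i in seq_len(nLayers)) {
        a <- agAddBias(tape, agMM(tape, a, P[[paste0("W", i)]]),
                       P[[paste0("b", i)]])
        if (i < nLayers) a <- agReLU(tape, a)
      }
      a
    },
    gru = {
      # X: list of T matrices (batch x nFeat)
      batch <- nrow(X[[1]])
      h <- agNode(tape, matrix(0, batch, ncol(P$Uz$val)))
      for (xt in X) {
        xn <- agNode(tape, xt)
        z <- agSigmoid(tape, agAddBias(tape,
               agAdd(tape, agMM(tape, xn, P$Wz), agMM(tape, h, P$Uz)), P$bz))
        r <- agSigmoid(tape, agAddBias(tape,
               agAdd(tape, agMM(tape, xn, P$Wr), agMM(tape, h, P$Ur)), P$br))
        hh <- agTanh(tape, agAddBias(tape,
                agAdd(tape, agMM(tape, xn, P$Wh),
                      agMM(tape, agMul(tape, r, h), P$Uh)), P$bh))
        h <- agAdd(tape, agMul(tape, agOneMinus(tape, z), h),
                   agMul(tape, z, hh))
      }
      agAddBias(tape, agMM(tape, h, P$Wo), P$bo)
    },
    transformer = {
      # X: (batch*T) x nFeat with attributes batch, tLen
      batch <- attr(X, "batch"); tLen <- attr(X, "tLen")
      d <- ncol(P$Win$val)
      nHeads <- hyper$nHeads %||% 4L
      nb <- hyper$nBlocks %||% 2L
      a <- agAddBias(tape, agMM(tape, agNode(tape, X), P$Win), P$bin)
      pe <- posEncoding(tLen, d)[rep(seq_len(tLen), batch), , drop = FALSE]
      a <- agAddConst(tape, a, pe)
      for (i in seq_len(nb)) {
        pre <- paste0("blk", i, ".")
        x1 <- agLayerNorm(tape, a, P[[paste0(pre, "g1")]],
                          P[[paste0(pre, "beta1")]])
        q <- agMM(tape, x1, P[[paste0(pre, "Wq")]])
        k <- agMM(tape, x1, P[[paste0(pre, "Wk")]])
        v <- agMM(tape, x1, P[[paste0(pre, "Wv")]])
        att <- agAttention(tape, q, k, v, batch, tLen, nHeads)
        att <- agAddBias(tape, agMM(tape, att, P[[paste0(pre, "Wo")]]),
                         P[[paste0(pre, "bo")]])
        a <- agAdd(tape, a, att)
        x2 <- agLayerNorm(tape, a, P[[paste0(pre, "g2")]],
                          P[[paste0(pre, "beta2")]])
        ff <- agAddBias(tape, agMM(tape, agReLU(tape, agAddBias(tape,
                agMM(tape, x2, P[[paste0(pre, "Wf1")]]),
                P[[paste0(pre, "bf1")]])), P[[paste0(pre, "Wf2")]]),
                P[[paste0(pre, "bf2")]])
        a <- agAdd(tape, a, ff)
      }
      pooled <- agSeqMean(tape, a, batch, tLen)
      agAddBias(tape, agMM(tape, pooled, P$Wout), P$bout)
    },
    cnn1d = {
      # X: batch x channels x L array
      nConv <- sum(grepl("^Wc", names(P)))
      pool <- hyper$pool %||% 4L
      a <- agNode(tape, X)
      for (i in seq_len(nConv)) {
        a <- agReLU(tape, agConv1d(tape, a, P[[paste0("Wc", i)]],
                                   P[[paste0("bc", i)]]))
        if (dim(a$val)[3] >= pool && i < nConv)
          a <- agAvgPool1d(tape, a, pool)
      }
      a <- agGlobalMean(tape, a)
      agAddBias(tape, agMM(tape, a, P$Wout), P$bout)
    })
}

# reshape a lagged feature matrix (samples x C*B*(nLags+1), lag fastest)
# into the per-family input layout
netPrepareInput <- function(family, X, hyper) {
  if (family == "mlp" || is.null(dim(X)) ) return(X)
  if (family %in% c("gru", "transformer")) {
    tLen <- hyper$tLen %||% 6L
    if (ncol(X) %% tLen != 0)
      stop("feature count not divisible by the number of time steps")
    nFeat <- ncol(X) %/% tLen
    steps <- lapply(seq_len(tLen), function(s)
      X[, seq(s, ncol(X), by = tLen), drop = FALSE])
    if (family == "gru") return(steps)
    flat <- matrix(0, nrow(X) * tLen, nFeat)
    for (s in seq_len(tLen)) flat[seq(s, nrow(flat), by = tLen), ] <- steps[[s]]
    attr(flat, "batch") <- nrow(X); attr(flat, "tLen") <- tLen
    return(flat)
  }
  if (family == "cnn1d" && is.matrix(X)) {
    # lagged feature matrix -> samples x units x time grid; the raw-EEG
    # path passes a samples x channels x timepoints array directly
    tLen <- hyper$tLen %||% 6L
    if (ncol(X) %% tLen != 0)
      stop("feature count not divisible by the number of time steps")
    nFeat <- ncol(X) %/% tLen
    out <- array(0, c(nrow(X), nFeat, tLen))
    for (f in seq_len(nFeat)) out[, f, ] <- X[, (f - 1L) * tLen + seq_len(tLen)]
    return(out)
  }
  X
}

netSubset <- function(family, Xp, rows) {
  if (family == "gru") return(lapply(Xp, function(m) m[rows, , drop = FALSE]))
  if (family == "transformer") {
    tLen <- attr(Xp, "tLen")
    sel <- as.vector(vapply(rows, function(r) (r - 1L) * tLen + seq_len(tLen),
                            integer(tLen)))
    out <- Xp[sel, , drop = FALSE]
    attr(out, "batch") <- length(rows); attr(out, "tLen") <- tLen
    return(out)
  }
  if (family == "cnn1d") return(Xp[rows, , , drop = FALSE])
  Xp[rows, , drop = FALSE]
}

netLossNode <- function(task, tape, z, y) {
  if (task == "classification") agBCEWithLogits(tape, z, y)
  else agMSE(tape, z, y)
}

netEvalLoss <- function(family, task, params, Xp, y, hyper) {
  tape <- agTape()
  P <- lapply(params, function(p) agParam(tape, p))
  z <- netForward(family, tape, P, Xp, hyper)
  as.numeric(netLossNode(task, tape, z, y)$val)
}

# Adam training with mini-batches and early stopping on validation loss
netTrain <- function(family, task, X, y, Xval, yval, hyper, seed) {
  maxEpochs <- hyper$maxEpochs %||% 200L
  patience <- hyper$patience %||% 10L
  batchSize <- hyper$batchSize %||% 32L
  lr <- hyper$lr %||% 1e-3
  n <- if (family == "gru") nrow(X[[1]])
       else if (family == "transformer") attr(X, "batch")
       else if (family == "cnn1d") dim(X)[1] else nrow(X)
  inputDim <- switch(family,
    mlp = ncol(X),
    gru = list(nFeat = ncol(X[[1]])),
    transformer = list(nFeat = ncol(X)),
    cnn1d = list(nChan = dim(X)[2]))
  withSeed(seed, {
    params <- netInitParams(family, inputDim, hyper)
    state <- adamInit(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    curve <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
    for (epoch in seq_len(maxEpochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batchSize)
      epochLoss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + batchSize - 1L, n)]
        tape <- agTape()
        P <- lapply(params, function(p) agParam(tape, p))
        z <- netForward(family, tape, P, netSubset(family, X, rows), hyper)
        loss <- netLossNode(task, tape, z, y[rows])
        agBackward(tape, loss)
        grads <- lapply(P, function(node) node$grad)
        params <- adamStep(params, grads, state, lr = lr)
        epochLoss <- epochLoss + as.numeric(loss$val) * length(rows)
      }
      valLoss <- netEvalLoss(family, task, params, Xval, yval, hyper)
      curve <- rbind(curve, data.frame(epoch = epoch,
                                       train = epochLoss / n, val = valLoss))
      if (valLoss < best$loss - 1e-9) {
        best <- list(loss = valLoss, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= patience) break
    }
    list(params = best$params, curve = curve, bestEpoch = best$epoch)
  })
}

netPredict <- function(family, task, params, Xp, hyper) {
  tape <- agTape()
  P <- lapply(params, function(p) agParam(tape, p))
  z <- as.numeric(netForward(family, tape, P, Xp, hyper)$val)
  if (task == "classification")
    factor(ifelse(z >= 0, "increase", "decrease"),
           levels = c("increase", "decrease"))
  else z
}
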