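# Minimal reverse-mode automatic differentiation on a tape of array nodes.
# Powers the neural model families (MLP, 1-D CNN, GRU, transformer); sizes
# are small (batches of 32, sequences of 6 steps), so plain R array ops on
# BLAS-backed matrices are adequate. Gradients are verified against finite
# differences in the test suite.

agTape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

agNode <- function(tape, val, backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- n
  n
}

agAcc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

agParam <- function(tape, val) agNode(tape, val)

agBackward <- function(tape, loss) {
  loss$grad <- array(1, dim = dim(loss$val) %||% length(loss$val))
  for (i in rev(seq_len(tape$n))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$backfn)) n$backfn(n$grad)
  }
}

agMM <- function(tape, a, b) {
  agNode(tape, a$val %*% b$val, function(g) {
    agAcc(a, g %*% t(b$val))
    agAcc(b, t(a$val) %*% g)
  })
}

agAddBias <- function(tape, a, bias) {   # a: n x m, bias: length-m vector
  agNode(tape, sweep(a$val, 2L, as.numeric(bias$val), "+"), function(g) {
    agAcc(a, g)
    agAcc(bias, colSums(g))
  })
}

agAdd <- function(tape, a, b) {
  agNode(tape, a$val + b$val, function(g) { agAcc(a, g); agAcc(b, g) })
}

agAddConst <- function(tape, a, k) {
  agNode(tape, a$val + k, function(g) agAcc(a, g))
}

agMul <- function(tape, a, b) {
  agNode(tape, a$val * b$val, function(g) {
    agAcc(a, g * b$val)
    agAcc(b, g * a$val)
  })
}

agOneMinus <- function(tape, a) {
  agNode(tape, 1 - a$val, function(g) agAcc(a, -g))
}

agReLU <- function(tape, a) {
  agNode(tape, pmax(a$val, 0), function(g) agAcc(a, g * (a$val > 0)))
}

agSigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  agNode(tape, s, function(g) agAcc(a, g * s * (1 - s)))
}

agTanh <- function(tape, a) {
  s <- tanh(a$val)
  agNode(tape, s, function(g) agAcc(a, g * (1 - s^2)))
}

# row-wise layer normalization with learned gain/offset
agLayerNorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$val
  m <- rowMeans(x)
  xc <- x - m
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, as.numeric(gamma$val), "*"), 2L,
             as.numeric(beta$val), "+")
  agNode(tape, y, function(g) {
    agAcc(gamma, colSums(g * xhat))
    agAcc(beta, colSums(g))
    gx <- sweep(g, 2L, as.numeric(gamma$val), "*")
    d <- ncol(x)
    gXhat <- gx * inv
    term <- rowMeans(gx * xhat) * inv
    agAcc(a, gXhat - rowMeans(gXhat) - xhat * term)
  })
}

# 1-D convolution: x (batch x inC x L), w (inC x k x outC), bias (outC)
agConv1d <- function(tape, x, w, bias) {
  xd <- dim(x$val); wd <- dim(w$val)
  batch <- xd[1]; inC <- xd[2]; L <- xd[3]; k <- wd[2]; outC <- wd[3]
  lOut <- L - k + 1L
  if (lOut < 1L) stop("conv1d kernel longer than the input")
  acc <- matrix(0, batch * lOut, outC)
  mats <- vector("list", k)
  for (dk in seq_len(k)) {
    xs <- x$val[, , dk:(dk + lOut - 1L), drop = FALSE]
    m <- matrix(aperm(xs, c(1, 3, 2)), batch * lOut, inC)
    mats[[dk]] <- m
    acc <- acc + m %*% w$val[, dk, ]
  }
  acc <- sweep(acc, 2L, as.numeric(bias$val), "+")
  y <- aperm(array(acc, c(batch, lOut, outC)), c(1, 3, 2))
  agNode(tape, y, function(g) {
    gm <- matrix(aperm(g, c(1, 3, 2)), batch * lOut, outC)
    agAcc(bias, colSums(gm))
    dw <- array(0, wd)
    dx <- array(0, xd)
    for (dk in seq_len(k)) {
      dw[, dk, ] <- t(mats[[dk]]) %*% gm
      dxs <- aperm(array(gm %*% t(w$val[, dk, ]), c(batch, lOut, inC)),
                   c(1, 3, 2))
      dx[, , dk:(dk + lOut - 1L)] <- dx[, , dk:(dk + lOut - 1L), drop = FALSE] + dxs
    }
    agAcc(w, dw)
    agAcc(x, dx)
  })
}

# non-overlapping average pooling along the last axis of (batch x C x L)
agAvgPool1d <- function(tape, x, factor) {
  xd <- dim(x$val)
  lOut <- xd[3] %/% factor
  y <- array(0, c(xd[1], xd[2], lOut))
  for (j in seq_len(lOut))
    y[, , j] <- apply(x$val[, , (j - 1L) * factor + seq_len(factor),
                            drop = FALSE], c(1, 2), mean)
  agNode(tape, y, function(g) {
    dx <- array(0, xd)
    for (j in seq_len(lOut))
      dx[, , (j - 1L) * factor + seq_len(factor)] <-
        array(rep(g[, , j] / factor, factor), c(xd[1], xd[2], factor))
    agAcc(x, dx)
  })
}

# mean over the last axis: (batch x C x L) -> (batch x C)
agGlobalMean <- function(tape, x) {
  xd <- dim(x$val)
  agNode(tape, apply(x$val, c(1, 2), mean), function(g) {
    agAcc(x, array(rep(g / xd[3], xd[3]), xd))
  })
}

# mean over tokens: rows of a (batch*T x d) matrix grouped per sample
agSeqMean <- function(tape, x, batch, tLen) {
  idx <- rep(seq_len(batch), each = tLen)
  y <- rowsum(x$val, idx) / tLen
  agNode(tape, y, function(g) {
    agAcc(x, g[idx, , drop = FALSE] / tLen)
  })
}

# multi-head scaled dot-product self-attention; q, k, v are (batch*T x d)
agAttention <- function(tape, q, k, v, batch, tLen, nHeads) {
  d <- ncol(q$val)
  dh <- d %/% nHeads
  scale <- 1 / sqrt(dh)
  out <- matrix(0, batch * tLen, d)
  attn <- vector("list", batch * nHeads)
  for (s in seq_len(batch)) {
    rows <- (s - 1L) * tLen + seq_len(tLen)
    for (h in seq_len(nHeads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      S <- (q$val[rows, cols, drop = FALSE] %*%
              t(k$val[rows, cols, drop = FALSE])) * scale
      S <- S - apply(S, 1L, max)
      A <- exp(S); A <- A / rowSums(A)
      attn[[(s - 1L) * nHeads + h]] <- A
      out[rows, cols] <- A %*% v$val[rows, cols, drop = FALSE]
    }
  }
  agNode(tape, out, function(g) {
    dq <- matrix(0, batch * tLen, d)
    dk <- matrix(0, batch * tLen, d)
    dv <- matrix(0, batch * tLen, d)
    for (s in seq_len(batch)) {
      rows <- (s - 1L) * tLen + seq_len(tLen)
      for (h in seq_len(nHeads)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        A <- attn[[(s - 1L) * nHeads + h]]
        gO <- g[rows, cols, drop = FALSE]
        Vs <- v$val[rows, cols, drop = FALSE]
        dv[rows, cols] <- t(A) %*% gO
        dA <- gO %*% t(Vs)
        dS <- A * (dA - rowSums(dA * A))
        dq[rows, cols] <- (dS %*% k$val[rows, cols, drop = FALSE]) * scale
        dk[rows, cols] <- (t(dS) %*% q$val[rows, cols, drop = FALSE]) * scale
      }
    }
    agAcc(q, dq); agAcc(k, dk); agAcc(v, dv)
  })
}

# mean binary cross-entropy on logits z (n x 1) against y in {0, 1}
agBCEWithLogits <- function(tape, z, y) {
  zv <- as.numeric(z$val)
  loss <- mean(pmax(zv, 0) - y * zv + log1p(exp(-abs(zv))))
  agNode(tape, matrix(loss, 1, 1), function(g) {
    p <- 1 / (1 + exp(-zv))
    agAcc(z, matrix((p - y) / length(y) * as.numeric(g), ncol = 1L))
  })
}

# mean squared error on predictions z (n x 1)
agMSE <- function(tape, z, y) {
  zv <- as.numeric(z$val)
  agNode(tape, matrix(mean((zv - y)^2), 1, 1), function(g) {
    agAcc(z, matrix(2 * (zv - y) / length(y) * as.numeric(g), ncol = 1L))
  })
}

# Adam step, updating the parameter list in place
adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

adamInit <- function(params) {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- lapply(params, function(p) p * 0)
  e$v <- lapply(params, function(p) p * 0)
  e
}
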