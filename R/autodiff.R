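# Minimal reverse-mode autodiff tape on dense matrices.
#
# The neural modules (encoder, decoder, training losses) build their forward
# pass out of the ops below; adBackward() walks the tape in reverse and
# accumulates gradients into every node reached from the loss. Attention is
# provided as fused ops (adTiedRowAttention, adBlockAttention) whose backward
# passes are hand-derived; all backward formulas are verified against central
# finite differences in the test suite.
#
# Layout conventions: an MSA representation lives in a single (N*L) x d
# matrix. "Species-major" stacks species blocks of L rows; "site-major"
# stacks site blocks of N rows. No op ever materializes an (N*L) x (N*L)
# attention map; the largest softmax input observed is tracked in
# .ad$maxSoftmaxElems so tests can assert the axial memory pattern.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$n <- 0L
.ad$enabled <- TRUE
.ad$maxSoftmaxElems <- 0L

adReset <- function(enabled = TRUE) {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  .ad$enabled <- isTRUE(enabled)
  invisible(NULL)
}

adGradEnabled <- function() .ad$enabled

.adNoteSoftmax <- function(nelem) {
  if (nelem > .ad$maxSoftmaxElems) .ad$maxSoftmaxElems <- nelem
}

adMaxSoftmaxElems <- function() .ad$maxSoftmaxElems
adResetSoftmaxStats <- function() { .ad$maxSoftmaxElems <- 0L; invisible(NULL) }

.adPush <- function(node) {
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) {
    .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  }
  .ad$tape[[n]] <- node
  .ad$n <- n
  node
}

.adNode <- function(val, parents = NULL, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  if (.ad$enabled) {
    node$parents <- parents
    node$backward <- backward
    .adPush(node)
  }
  node
}

adLeaf <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  .adNode(x)
}

.adAcc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

adBackward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  n <- .ad$n
  tape <- .ad$tape
  for (i in seq.int(n, 1L)) {
    node <- tape[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) {
      node$backward(node)
    }
  }
  invisible(NULL)
}

# ---- elementwise / linear ops ------------------------------------------

adMM <- function(a, b) {
  .adNode(a$val %*% b$val, list(a, b), function(n) {
    .adAcc(a, n$grad %*% t(b$val))
    .adAcc(b, crossprod(a$val, n$grad))
  })
}

# a %*% t(b)
adMMnt <- function(a, b) {
  .adNode(tcrossprod(a$val, b$val), list(a, b), function(n) {
    .adAcc(a, n$grad %*% b$val)
    .adAcc(b, crossprod(n$grad, a$val))
  })
}

adAdd <- function(a, b) {
  .adNode(a$val + b$val, list(a, b), function(n) {
    .adAcc(a, n$grad)
    .adAcc(b, n$grad)
  })
}

adSub <- function(a, b) {
  .adNode(a$val - b$val, list(a, b), function(n) {
    .adAcc(a, n$grad)
    .adAcc(b, -n$grad)
  })
}

adMul <- function(a, b) {
  .adNode(a$val * b$val, list(a, b), function(n) {
    .adAcc(a, n$grad * b$val)
    .adAcc(b, n$grad * a$val)
  })
}

# bias is a 1 x d row vector broadcast over the rows of a
adAddBias <- function(a, bias) {
  .adNode(sweep(a$val, 2L, as.vector(bias$val), "+"), list(a, bias), function(n) {
    .adAcc(a, n$grad)
    .adAcc(bias, matrix(colSums(n$grad), 1L))
  })
}

adAffine <- function(a, mult, add = 0) {
  .adNode(mult * a$val + add, list(a), function(n) {
    .adAcc(a, mult * n$grad)
  })
}

adRelu <- function(a) {
  mask <- a$val > 0
  .adNode(a$val * mask, list(a), function(n) .adAcc(a, n$grad * mask))
}

adSigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  .adNode(s, list(a), function(n) .adAcc(a, n$grad * s * (1 - s)))
}

adGelu <- function(a) {
  x <- a$val
  ph <- stats::pnorm(x)
  .adNode(x * ph, list(a), function(n) {
    .adAcc(a, n$grad * (ph + x * stats::dnorm(x)))
  })
}

adSoftmaxRows <- function(a) {
  .adNoteSoftmax(length(a$val))
  x <- a$val - apply(a$val, 1L, max)
  e <- exp(x)
  p <- e / rowSums(e)
  .adNode(p, list(a), function(n) {
    g <- n$grad
    .adAcc(a, p * (g - rowSums(g * p)))
  })
}

# log-softmax of a single-column vector
adLogSoftmaxCol <- function(a) {
  x <- as.vector(a$val)
  m <- max(x)
  ls <- x - m - log(sum(exp(x - m)))
  .adNode(matrix(ls, ncol = 1L), list(a), function(n) {
    g <- n$grad
    .adAcc(a, g - exp(ls) * sum(g))
  })
}

adPick <- function(a, i) {
  .adNode(a$val[i, 1L, drop = FALSE], list(a), function(n) {
    g <- matrix(0, nrow(a$val), ncol(a$val))
    g[i, 1L] <- n$grad[1L, 1L]
    .adAcc(a, g)
  })
}

adLayerNorm <- function(a, gain, bias, eps = 1e-5) {
  x <- a$val
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  invsd <- 1 / sqrt(v + eps)
  xhat <- xc * invsd
  y <- sweep(sweep(xhat, 2L, as.vector(gain$val), "*"), 2L, as.vector(bias$val), "+")
  .adNode(y, list(a, gain, bias), function(n) {
    g <- n$grad
    dxhat <- sweep(g, 2L, as.vector(gain$val), "*")
    .adAcc(a, invsd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)))
    .adAcc(gain, matrix(colSums(g * xhat), 1L))
    .adAcc(bias, matrix(colSums(g), 1L))
  })
}

adColMeans <- function(a) {
  nr <- nrow(a$val)
  .adNode(matrix(colMeans(a$val), 1L), list(a), function(n) {
    .adAcc(a, matrix(rep(n$grad / nr, each = nr), nr))
  })
}

adMeanAll <- function(a) {
  k <- length(a$val)
  .adNode(matrix(mean(a$val), 1L, 1L), list(a), function(n) {
    .adAcc(a, matrix(n$grad[1L, 1L] / k, nrow(a$val), ncol(a$val)))
  })
}

adSumAll <- function(a) {
  .adNode(matrix(sum(a$val), 1L, 1L), list(a), function(n) {
    .adAcc(a, matrix(n$grad[1L, 1L], nrow(a$val), ncol(a$val)))
  })
}

adRbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$val)
  nr <- vapply(vals, nrow, 1L)
  off <- cumsum(c(0L, nr))
  .adNode(do.call(rbind, vals), nodes, function(n) {
    for (i in seq_along(nodes)) {
      .adAcc(nodes[[i]], n$grad[(off[i] + 1L):off[i + 1L], , drop = FALSE])
    }
  })
}

adCbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$val)
  nc <- vapply(vals, ncol, 1L)
  off <- cumsum(c(0L, nc))
  .adNode(do.call(cbind, vals), nodes, function(n) {
    for (i in seq_along(nodes)) {
      .adAcc(nodes[[i]], n$grad[, (off[i] + 1L):off[i + 1L], drop = FALSE])
    }
  })
}

adGatherRows <- function(a, idx) {
  .adNode(a$val[idx, , drop = FALSE], list(a), function(n) {
    acc <- rowsum(n$grad, idx)
    g <- matrix(0, nrow(a$val), ncol(a$val))
    g[as.integer(rownames(acc)), ] <- acc
    .adAcc(a, g)
  })
}

# ---- fused attention ops ------------------------------------------------

# Self-attention over N rows within each of B contiguous blocks (site-major
# layout: block b holds rows (b-1)*N + 1..N). Q, K, V are (B*N) x dh.
adBlockAttention <- function(q, k, v, nBlocks, blockSize, scale) {
  Qv <- q$val; Kv <- k$val; Vv <- v$val
  BN <- nrow(Qv)
  N <- blockSize
  stopifnot(BN == nBlocks * N)
  kidx <- vector("list", N)
  S <- matrix(0, BN, N)
  base <- rep((0:(nBlocks - 1L)) * N, each = N)
  for (j in seq_len(N)) {
    kidx[[j]] <- base + j
    S[, j] <- rowSums(Qv * Kv[kidx[[j]], , drop = FALSE]) * scale
  }
  .adNoteSoftmax(length(S))
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  A <- E / rowSums(E)
  O <- matrix(0, BN, ncol(Vv))
  for (j in seq_len(N)) {
    O <- O + A[, j] * Vv[kidx[[j]], , drop = FALSE]
  }
  .adNode(O, list(q, k, v), function(n) {
    g <- n$grad
    dA <- matrix(0, BN, N)
    dV <- matrix(0, BN, ncol(Vv))
    for (j in seq_len(N)) {
      dA[, j] <- rowSums(g * Vv[kidx[[j]], , drop = FALSE])
      acc <- rowsum(A[, j] * g, kidx[[j]])
      dV[as.integer(rownames(acc)), ] <- dV[as.integer(rownames(acc)), ] + acc
    }
    dS <- A * (dA - rowSums(dA * A))
    dQ <- matrix(0, BN, ncol(Qv))
    dK <- matrix(0, BN, ncol(Kv))
    for (j in seq_len(N)) {
      dQ <- dQ + (dS[, j] * scale) * Kv[kidx[[j]], , drop = FALSE]
      acc <- rowsum((dS[, j] * scale) * Qv, kidx[[j]])
      dK[as.integer(rownames(acc)), ] <- dK[as.integer(rownames(acc)), ] + acc
    }
    .adAcc(q, dQ); .adAcc(k, dK); .adAcc(v, dV)
  })
}

# Tied row attention: one L x L attention map shared by all N species
# (species-major layout; logits summed over species). Q, K, V are (N*L) x dh.
adTiedRowAttention <- function(q, k, v, nSpecies, L, scale) {
  Qv <- q$val; Kv <- k$val; Vv <- v$val
  dh <- ncol(Qv)
  rows <- function(i) ((i - 1L) * L + 1L):(i * L)
  Qcat <- matrix(0, L, nSpecies * dh)
  Kcat <- matrix(0, L, nSpecies * dh)
  for (i in seq_len(nSpecies)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    Qcat[, cols] <- Qv[rows(i), , drop = FALSE]
    Kcat[, cols] <- Kv[rows(i), , drop = FALSE]
  }
  S <- tcrossprod(Qcat, Kcat) * scale
  .adNoteSoftmax(length(S))
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  A <- E / rowSums(E)
  O <- matrix(0, nrow(Vv), ncol(Vv))
  for (i in seq_len(nSpecies)) {
    O[rows(i), ] <- A %*% Vv[rows(i), , drop = FALSE]
  }
  .adNode(O, list(q, k, v), function(n) {
    g <- n$grad
    dA <- matrix(0, L, L)
    dV <- matrix(0, nrow(Vv), ncol(Vv))
    for (i in seq_len(nSpecies)) {
      gi <- g[rows(i), , drop = FALSE]
      Vi <- Vv[rows(i), , drop = FALSE]
      dA <- dA + tcrossprod(gi, Vi)
      dV[rows(i), ] <- crossprod(A, gi)
    }
    dS <- A * (dA - rowSums(dA * A))
    dQcat <- (dS %*% Kcat) * scale
    dKcat <- (crossprod(dS, Qcat)) * scale
    dQ <- matrix(0, nrow(Qv), dh)
    dK <- matrix(0, nrow(Kv), dh)
    for (i in seq_len(nSpecies)) {
      cols <- ((i - 1L) * dh + 1L):(i * dh)
      dQ[rows(i), ] <- dQcat[, cols, drop = FALSE]
      dK[rows(i), ] <- dKcat[, cols, drop = FALSE]
    }
    .adAcc(q, dQ); .adAcc(k, dK); .adAcc(v, dV)
  })
}
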