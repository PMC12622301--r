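# GTR+I+G transition probabilities and Felsenstein pruning log-likelihood.
# The rate matrix is diagonalized once per model through the pi^(1/2)
# symmetrization, so P(t) = exp(Qt) costs one 4x4 congruence per branch.
# Partial likelihoods are per-node 4 x L matrices with per-site scaling to
# avoid underflow; gaps are missing data (all-ones leaf vectors).

#' Discrete gamma category rates
#'
#' Median-of-category discretization of the mean-1 gamma distribution with
#' shape `gammaShape`, renormalized so the category mean is exactly 1.
#' `gammaShape = Inf` (or a single category) gives rate 1.
#'
#' @param model a [GTRModel][GTRModel-class].
#' @return Numeric vector of `nCategories` positive rates with mean 1.
#' @export
gammaCategoryRates <- function(model) {
  K <- model@nCategories
  a <- model@gammaShape
  if (K == 1L || !is.finite(a)) return(rep(1, K))
  q <- stats::qgamma((2 * seq_len(K) - 1) / (2 * K), shape = a, rate = a)
  q * K / sum(q)
}

#' Normalized GTR rate matrix
#'
#' Builds `Q[i, j] = r_ij * pi_j` (i != j) with diagonal minus the row
#' sums, scaled so the expected substitution rate at stationarity,
#' `-sum_i pi_i Q_ii`, equals 1. The result satisfies detailed balance
#' (`pi_i Q_ij = pi_j Q_ji`) and `pi Q = 0`.
#'
#' @param model a [GTRModel][GTRModel-class].
#' @return A list with `Q` (4x4), `pi`, and the symmetric
#'   eigendecomposition (`values`, `vectors`, `piHalf`) used by
#'   [transitionProbs()].
#' @export
gtrRateMatrix <- function(model) {
  r <- model@rates
  pi <- model@baseFreqs
  R <- matrix(0, 4L, 4L, dimnames = list(names(pi), names(pi)))
  R["A", "C"] <- R["C", "A"] <- r[["AC"]]
  R["A", "G"] <- R["G", "A"] <- r[["AG"]]
  R["A", "T"] <- R["T", "A"] <- r[["AT"]]
  R["C", "G"] <- R["G", "C"] <- r[["CG"]]
  R["C", "T"] <- R["T", "C"] <- r[["CT"]]
  R["G", "T"] <- R["T", "G"] <- r[["GT"]]
  Q <- R %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  piHalf <- sqrt(pi)
  B <- diag(piHalf) %*% Q %*% diag(1 / piHalf)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(Q = Q, pi = pi, values = eig$values, vectors = eig$vectors, piHalf = piHalf)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the symmetric eigendecomposition of the normalized GTR
#' generator. Rows sum to 1; P(0) is the identity; as t grows every row
#' tends to the stationary distribution.
#'
#' @param rateMatrix result of [gtrRateMatrix()].
#' @param t branch length in expected substitutions per site, >= 0.
#' @return A 4x4 row-stochastic matrix.
#' @export
transitionProbs <- function(rateMatrix, t) {
  if (t < 0) stop("branch length must be nonnegative")
  if (t == 0) {
    P <- diag(4L)
    dimnames(P) <- dimnames(rateMatrix$Q)
    return(P)
  }
  U <- rateMatrix$vectors
  P <- diag(1 / rateMatrix$piHalf) %*% U %*% (exp(rateMatrix$values * t) * t(U)) %*%
    diag(rateMatrix$piHalf)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(rateMatrix$Q)
  P
}

# partial likelihoods for one rate category; returns list(partial at root
# as 4 x L, logScale per site)
.pruneCategory <- function(tree, leafCodes, rateMatrix, rate) {
  nt <- nrow(leafCodes)
  L <- ncol(leafCodes)
  nNodes <- nt + tree$Nnode
  partial <- vector("list", nNodes)
  for (i in seq_len(nt)) {
    m <- matrix(0, 4L, L)
    codes <- leafCodes[i, ]
    gap <- codes == 4L
    if (any(!gap)) m[cbind(codes[!gap] + 1L, which(!gap))] <- 1
    m[, gap] <- 1
    partial[[i]] <- m
  }
  logScale <- numeric(L)
  ord <- ape::reorder.phylo(tree, "postorder")
  Pcache <- list()
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    t <- ord$edge.length[k] * rate
    key <- sprintf("%.12g", t)
    P <- Pcache[[key]]
    if (is.null(P)) {
      P <- transitionProbs(rateMatrix, t)
      Pcache[[key]] <- P
    }
    contrib <- P %*% partial[[ch]]
    if (is.null(partial[[p]])) {
      partial[[p]] <- contrib
    } else {
      partial[[p]] <- partial[[p]] * contrib
      mx <- apply(partial[[p]], 2L, max)
      nz <- mx > 0
      if (any(nz)) {
        partial[[p]][, nz] <- sweep(partial[[p]][, nz, drop = FALSE], 2L, mx[nz], "/")
        logScale[nz] <- logScale[nz] + log(mx[nz])
      }
    }
  }
  root <- nt + 1L
  list(partial = partial[[root]], logScale = logScale)
}

#' Felsenstein pruning log-likelihood under GTR+I+G
#'
#' Computes `log P(alignment | tree, model)` by post-order accumulation of
#' partial likelihoods. Per site, the likelihood is the I+G mixture:
#' `pInv` times the invariant-site contribution (nonzero only when all
#' non-gap states in the column agree) plus `1 - pInv` times the average
#' over the discrete gamma categories. Gaps are treated as missing data.
#' Returns `-Inf` when the likelihood is exactly zero. The value is
#' invariant to the rooting used for traversal (reversibility).
#'
#' @param tree `ape::phylo` with branch lengths; tip labels must match the
#'   alignment labels.
#' @param msa a [PhyloMSA][PhyloMSA-class].
#' @param model a [GTRModel][GTRModel-class].
#' @return The total log-likelihood (numeric scalar).
#' @export
felsensteinLogLik <- function(tree, msa, model) {
  stopifnot(inherits(tree, "phylo"))
  labels <- msaLabels(msa)
  if (!setequal(tree$tip.label, labels)) {
    stop("tree/alignment label mismatch; tree-only: {",
         paste(setdiff(tree$tip.label, labels), collapse = ","),
         "}, alignment-only: {",
         paste(setdiff(labels, tree$tip.label), collapse = ","), "}")
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must have branch lengths")
  }
  codes <- msaCodes(msa)[tree$tip.label, , drop = FALSE]
  L <- ncol(codes)
  rm <- gtrRateMatrix(model)
  rates <- gammaCategoryRates(model)

  siteLik <- numeric(L)  # gamma-mixture part, in linear scale with shared log offset
  logOffset <- matrix(0, length(rates), L)
  perCat <- matrix(0, length(rates), L)
  for (k in seq_along(rates)) {
    pr <- .pruneCategory(tree, codes, rm, rates[k])
    perCat[k, ] <- as.vector(rm$pi %*% pr$partial)
    logOffset[k, ] <- pr$logScale
  }
  # combine categories: per site, log( (1/K) sum_k exp(logOffset) * perCat )
  K <- length(rates)
  logCat <- log(perCat) + logOffset  # -Inf where perCat == 0
  mx <- apply(logCat, 2L, max)
  gammaPart <- ifelse(is.finite(mx),
                      mx + log(colSums(exp(sweep(logCat, 2L, mx, "-")))) - log(K),
                      -Inf)

  pInv <- model@pInv
  if (pInv > 0) {
    invPart <- numeric(L)
    for (x in 1:4) {
      compatible <- colSums(codes == (x - 1L) | codes == 4L) == nrow(codes)
      invPart[compatible] <- invPart[compatible] + rm$pi[x]
    }
    siteLog <- log(pInv * invPart + (1 - pInv) * exp(pmin(gammaPart, 700)))
    # where gammaPart is large-negative but invPart 0, fall back to gamma part
    zeroInv <- invPart == 0
    siteLog[zeroInv] <- log1p(-pInv) + gammaPart[zeroInv]
  } else {
    siteLog <- gammaPart
  }
  sum(siteLog)
}

#' Assign branch lengths to a topology
#'
#' `mode = "fixed"` sets every branch to `fixedLength` (default 0.1), the
#' cheap setting used when scoring sampled topologies during search.
#' `mode = "optimize"` runs round-robin per-branch golden-section
#' maximization of the pruning log-likelihood (bounded line search per
#' branch) until a sweep improves the log-likelihood by less than `tol`
#' or `maxSweeps` sweeps are done; the log-likelihood never decreases
#' across sweeps.
#'
#' @param tree `ape::phylo` topology (lengths present or not).
#' @param msa alignment used for the likelihood (optimize mode).
#' @param model substitution model (optimize mode).
#' @param mode `"fixed"` or `"optimize"`.
#' @param fixedLength branch length used by fixed mode.
#' @param maxSweeps,tol optimization controls.
#' @return The tree with `edge.length` set.
#' @export
assignBranchLengths <- function(tree, msa = NULL, model = NULL,
                                mode = c("fixed", "optimize"),
                                fixedLength = 0.1, maxSweeps = 5L, tol = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (mode == "fixed") {
    tree$edge.length <- rep(fixedLength, nrow(tree$edge))
    return(tree)
  }
  stopifnot(!is.null(msa), !is.null(model))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(fixedLength, nrow(tree$edge))
  cur <- felsensteinLogLik(tree, msa, model)
  for (sweep in seq_len(maxSweeps)) {
    before <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        felsensteinLogLik(tree, msa, model)
      }
      opt <- stats::optimize(f, interval = c(1e-8, 10), maximum = TRUE, tol = 1e-6)
      if (opt$objective >= cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - before < tol) break
  }
  tree
}
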