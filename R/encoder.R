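# Axial-attention MSA encoder. An N x L alignment is embedded per site
# (one-hot symbol + learned site-position embedding, through a
# GELU-activated MLP) and passed through nLayers blocks of
# tied-row-attention -> column-attention -> feed-forward, each as a
# pre-norm residual. Representations are kept as a single (N*L) x d matrix
# in species-major layout; attention memory follows the axial
# O(L*N^2 + L^2) pattern (no full (N*L)^2 map is ever formed).

.layoutSiteMajor <- function(N, L) {
  r <- seq_len(N * L)
  p <- (r - 1L) %/% N + 1L
  i <- (r - 1L) %% N + 1L
  (i - 1L) * L + p
}

.layoutSpeciesMajor <- function(N, L) {
  r <- seq_len(N * L)
  i <- (r - 1L) %/% L + 1L
  p <- (r - 1L) %% L + 1L
  (p - 1L) * N + i
}

.initParams <- function(cfg) {
  d <- cfg$dModel; H <- cfg$nHeads; dh <- d %/% H
  hid <- cfg$hiddenMult * d
  p <- list()
  gl <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  }
  zeros <- function(nin, nout) matrix(0, nin, nout)
  ones <- function(nout) matrix(1, 1L, nout)

  p[["embed.W"]] <- gl(5L, d)
  p[["embed.pos"]] <- matrix(stats::rnorm(cfg$maxLen * d, sd = 0.02), cfg$maxLen, d)
  p[["embed.W1"]] <- gl(d, hid); p[["embed.b1"]] <- zeros(1L, hid)
  p[["embed.W2"]] <- gl(hid, d); p[["embed.b2"]] <- zeros(1L, d)

  for (l in seq_len(cfg$nLayers)) {
    pre <- sprintf("layer%d.", l)
    for (blk in c("row", "col")) {
      for (h in seq_len(H)) {
        p[[paste0(pre, blk, ".Wq.", h)]] <- gl(d, dh)
        p[[paste0(pre, blk, ".Wk.", h)]] <- gl(d, dh)
        p[[paste0(pre, blk, ".Wv.", h)]] <- gl(d, dh)
      }
      p[[paste0(pre, blk, ".Wo")]] <- gl(d, d)
      p[[paste0(pre, blk, ".ln.g")]] <- ones(d)
      p[[paste0(pre, blk, ".ln.b")]] <- zeros(1L, d)
    }
    p[[paste0(pre, "ffn.W1")]] <- gl(d, hid); p[[paste0(pre, "ffn.b1")]] <- zeros(1L, hid)
    p[[paste0(pre, "ffn.W2")]] <- gl(hid, d); p[[paste0(pre, "ffn.b2")]] <- zeros(1L, d)
    p[[paste0(pre, "ffn.ln.g")]] <- ones(d); p[[paste0(pre, "ffn.ln.b")]] <- zeros(1L, d)
  }

  # decoder: child-fusion gate, ancestral-context cross-attention,
  # context-integration gate, per-site evaluator MLP
  p[["dec.gate1.W"]] <- gl(d, d); p[["dec.gate1.b"]] <- zeros(1L, d)
  p[["dec.ctx.Wq"]] <- gl(d, d); p[["dec.ctx.Wk"]] <- gl(d, d)
  p[["dec.ctx.Wv"]] <- gl(d, d); p[["dec.ctx.Wo"]] <- gl(d, d)
  p[["dec.gate2.W"]] <- gl(d, d); p[["dec.gate2.b"]] <- zeros(1L, d)
  p[["dec.eval.W1"]] <- gl(d, hid); p[["dec.eval.b1"]] <- zeros(1L, hid)
  p[["dec.eval.W2"]] <- gl(hid, 1L); p[["dec.eval.b2"]] <- zeros(1L, 1L)
  p
}

#' Create a learnable neighbor-joining model
#'
#' Initializes encoder and decoder weights (Glorot normal) for the given
#' architecture. The defaults are deliberately small so that training and
#' inference are practical on a single CPU; every dimension can be raised
#' for larger studies.
#'
#' @param dModel representation width d (divisible by `nHeads`).
#' @param nLayers number of axial attention blocks.
#' @param nHeads attention heads per block.
#' @param hiddenMult MLP expansion factor.
#' @param maxLen maximum alignment length supported by the learned
#'   positional embedding.
#' @param seed optional integer seed for weight initialization.
#' @return A [NeuralNJModel][NeuralNJModel-class].
#' @examples
#' m <- neuralNJModel(dModel = 8, nHeads = 2, seed = 1)
#' @export
neuralNJModel <- function(dModel = 16L, nLayers = 1L, nHeads = 2L,
                          hiddenMult = 2L, maxLen = 1024L, seed = NULL) {
  if (dModel %% nHeads != 0) stop("dModel must be divisible by nHeads")
  cfg <- list(dModel = as.integer(dModel), nLayers = as.integer(nLayers),
              nHeads = as.integer(nHeads), hiddenMult = as.integer(hiddenMult),
              maxLen = as.integer(maxLen))
  if (!is.null(seed)) set.seed(seed)
  new("NeuralNJModel", config = cfg, params = .initParams(cfg))
}

# wrap raw weight matrices as tape leaves, once per forward pass
.wrapParams <- function(params) lapply(params, adLeaf)

.adAttentionBlock <- function(x, P, pre, blk, cfg, N, L) {
  d <- cfg$dModel; H <- cfg$nHeads; dh <- d %/% H
  xn <- adLayerNorm(x, P[[paste0(pre, blk, ".ln.g")]], P[[paste0(pre, blk, ".ln.b")]])
  if (blk == "col") {
    xn <- adGatherRows(xn, .layoutSiteMajor(N, L))
  }
  heads <- vector("list", H)
  for (h in seq_len(H)) {
    q <- adMM(xn, P[[paste0(pre, blk, ".Wq.", h)]])
    k <- adMM(xn, P[[paste0(pre, blk, ".Wk.", h)]])
    v <- adMM(xn, P[[paste0(pre, blk, ".Wv.", h)]])
    heads[[h]] <- if (blk == "row") {
      adTiedRowAttention(q, k, v, N, L, 1 / sqrt(N * dh))
    } else {
      adBlockAttention(q, k, v, nBlocks = L, blockSize = N, 1 / sqrt(dh))
    }
  }
  o <- adMM(adCbind(heads), P[[paste0(pre, blk, ".Wo")]])
  if (blk == "col") {
    o <- adGatherRows(o, .layoutSpeciesMajor(N, L))
  }
  adAdd(x, o)
}

# forward pass of the encoder on wrapped params; codes is the N x L
# integer matrix; returns the (N*L) x d species-major representation node
.adEncode <- function(P, codes, cfg) {
  N <- nrow(codes); L <- ncol(codes)
  if (L > cfg$maxLen) {
    stop(sprintf("alignment length %d exceeds the model's maxLen %d", L, cfg$maxLen))
  }
  onehot <- matrix(0, N * L, 5L)
  flat <- as.vector(t(codes))  # species-major: species i rows (i-1)L+1..iL
  onehot[cbind(seq_len(N * L), flat + 1L)] <- 1
  x <- adMM(adLeaf(onehot), P[["embed.W"]])
  pos <- adGatherRows(P[["embed.pos"]], rep(seq_len(L), times = N))
  x <- adAdd(x, pos)
  x <- adAddBias(adMM(x, P[["embed.W1"]]), P[["embed.b1"]])
  x <- adGelu(x)
  x <- adAddBias(adMM(x, P[["embed.W2"]]), P[["embed.b2"]])

  for (l in seq_len(cfg$nLayers)) {
    pre <- sprintf("layer%d.", l)
    x <- .adAttentionBlock(x, P, pre, "row", cfg, N, L)
    x <- .adAttentionBlock(x, P, pre, "col", cfg, N, L)
    xn <- adLayerNorm(x, P[[paste0(pre, "ffn.ln.g")]], P[[paste0(pre, "ffn.ln.b")]])
    ff <- adAddBias(adMM(xn, P[[paste0(pre, "ffn.W1")]]), P[[paste0(pre, "ffn.b1")]])
    ff <- adGelu(ff)
    ff <- adAddBias(adMM(ff, P[[paste0(pre, "ffn.W2")]]), P[[paste0(pre, "ffn.b2")]])
    x <- adAdd(x, ff)
  }
  x
}

#' Encode an alignment into per-species, per-site representations
#'
#' Runs the axial-attention encoder forward and returns the representation
#' tensor H. Deterministic given the model weights; equivariant under
#' species permutation (there is no species-identity positional signal).
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param msa a [PhyloMSA][PhyloMSA-class].
#' @return A numeric array of dimension (N, L, dModel) with taxon labels
#'   on the first dimension.
#' @export
encodeMSA <- function(model, msa) {
  codes <- msaCodes(msa)
  N <- nrow(codes); L <- ncol(codes)
  adReset(enabled = FALSE)
  P <- .wrapParams(model@params)
  hFlat <- .adEncode(P, codes, model@config)$val
  H <- array(0, dim = c(N, L, model@config$dModel),
             dimnames = list(rownames(codes), NULL, NULL))
  for (i in seq_len(N)) {
    H[i, , ] <- hFlat[((i - 1L) * L + 1L):(i * L), ]
  }
  H
}
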