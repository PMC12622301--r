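# Tree decoder: topology-aware parent-node representation estimation and
# subtree scoring. A subtree is represented by an L x d matrix; joining
# candidates (l, r) are estimated in two gated stages — site-wise fusion of
# the children, then integration of an ancestral context obtained by
# cross-attention of the fused representation against the remaining active
# subtrees (mean-pooled over sites) — and the evaluator MLP maps the
# parent representation to a scalar priority score (mean over sites).
# Pairs are canonicalized by their sorted member sets, which makes the
# antisymmetric fusion gate (h_l - h_r) order-deterministic.

.memberKey <- function(members) paste(sort(members), collapse = ",")

# ---- tape-level pieces (used by construction and training) -------------

.adFuse <- function(P, hl, hr) {
  z <- adSigmoid(adAddBias(adMM(adSub(hl, hr), P[["dec.gate1.W"]]), P[["dec.gate1.b"]]))
  ht <- adAdd(adMul(z, hl), adMul(adAffine(z, -1, 1), hr))
  list(z = z, ht = ht)
}

# others: list of pooled 1 x d subtree nodes (already mean-pooled over sites)
.adContext <- function(P, ht, othersPooled) {
  if (!length(othersPooled)) stop("ancestral context needs at least one other subtree")
  d <- ncol(ht$val)
  keys <- adRbind(othersPooled)
  q <- adMM(ht, P[["dec.ctx.Wq"]])
  k <- adMM(keys, P[["dec.ctx.Wk"]])
  v <- adMM(keys, P[["dec.ctx.Wv"]])
  a <- adSoftmaxRows(adAffine(adMMnt(q, k), 1 / sqrt(d)))
  adMM(adMM(a, v), P[["dec.ctx.Wo"]])
}

.adIntegrate <- function(P, ht, hrest) {
  w <- adSigmoid(adAddBias(adMM(hrest, P[["dec.gate2.W"]]), P[["dec.gate2.b"]]))
  hx <- adAdd(adMul(w, ht), adMul(adAffine(w, -1, 1), hrest))
  list(w = w, hx = hx)
}

.adScore <- function(P, hx) {
  h <- adGelu(adAddBias(adMM(hx, P[["dec.eval.W1"]]), P[["dec.eval.b1"]]))
  adMeanAll(adAddBias(adMM(h, P[["dec.eval.W2"]]), P[["dec.eval.b2"]]))
}

# Score every unordered pair of active subtrees. reps: list of L x d
# nodes; members: list of character vectors. Returns pair indices in
# canonical order plus score nodes and the parent representation nodes
# (the executed pair's hx becomes the new subtree representation).
.adScorePairs <- function(P, reps, members) {
  k <- length(reps)
  stopifnot(k >= 2L)
  keys <- vapply(members, .memberKey, "")
  ord <- order(keys)
  pairs <- list(); scores <- list(); parents <- list()
  if (k == 2L) {
    # forced final join: no context set, no score needed
    i <- ord[1L]; j <- ord[2L]
    fused <- .adFuse(P, reps[[i]], reps[[j]])
    return(list(pairs = matrix(c(i, j), 1L), scores = list(NULL),
                parents = list(fused$ht)))
  }
  pooled <- lapply(reps, adColMeans)
  n <- 0L
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      i <- ord[a]; j <- ord[b]
      n <- n + 1L
      fused <- .adFuse(P, reps[[i]], reps[[j]])
      hrest <- .adContext(P, fused$ht, pooled[setdiff(seq_len(k), c(i, j))])
      hx <- .adIntegrate(P, fused$ht, hrest)$hx
      pairs[[n]] <- c(i, j)
      scores[[n]] <- .adScore(P, hx)
      parents[[n]] <- hx
    }
  }
  list(pairs = do.call(rbind, pairs), scores = scores, parents = parents)
}

# ---- exported numeric surface ------------------------------------------

#' Gated fusion of two child subtree representations
#'
#' Site-wise gate `z = sigmoid(Linear(h_l - h_r))` and convex combination
#' `hTilde = z * h_l + (1 - z) * h_r`. Every component of `hTilde` lies
#' between the corresponding components of the two inputs.
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param hl,hr L x d numeric matrices (subtree representations).
#' @return A list with matrices `z` (gates, in (0,1)) and `hTilde`.
#' @export
fuseChildren <- function(model, hl, hr) {
  stopifnot(identical(dim(hl), dim(hr)))
  adReset(enabled = FALSE)
  P <- .wrapParams(model@params)
  out <- .adFuse(P, adLeaf(hl), adLeaf(hr))
  list(z = out$z$val, hTilde = out$ht$val)
}

#' Ancestral context by cross-attention over the remaining subtrees
#'
#' Uses the fused representation as per-site queries against the other
#' active subtrees, each mean-pooled over sites into a single key/value
#' vector. Invariant to the order of `others`.
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param hTilde L x d fused child representation.
#' @param others nonempty list of L x d matrices for the remaining
#'   subtrees.
#' @return An L x d matrix `hRest`.
#' @export
ancestralContext <- function(model, hTilde, others) {
  if (!length(others)) stop("ancestral context needs at least one other subtree")
  adReset(enabled = FALSE)
  P <- .wrapParams(model@params)
  pooled <- lapply(others, function(h) adColMeans(adLeaf(h)))
  .adContext(P, adLeaf(hTilde), pooled)$val
}

#' Integrate fused children with the ancestral context
#'
#' Site-wise gate `w = sigmoid(Linear(hRest))` and convex combination
#' `hX = w * hTilde + (1 - w) * hRest`.
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param hTilde,hRest L x d matrices.
#' @return A list with matrices `w` and `hX`.
#' @export
integrateContext <- function(model, hTilde, hRest) {
  stopifnot(identical(dim(hTilde), dim(hRest)))
  adReset(enabled = FALSE)
  P <- .wrapParams(model@params)
  out <- .adIntegrate(P, adLeaf(hTilde), adLeaf(hRest))
  list(w = out$w$val, hX = out$hx$val)
}

#' Priority score of a candidate parent representation
#'
#' A per-site MLP maps each site vector of `hX` to a scalar; the score is
#' the mean over sites (so it is invariant to site order).
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param hX L x d matrix.
#' @return A single numeric score.
#' @export
scoreSubtree <- function(model, hX) {
  adReset(enabled = FALSE)
  P <- .wrapParams(model@params)
  .adScore(P, adLeaf(hX))$val[1L, 1L]
}

#' Enumerate and score all candidate subtree pairs
#'
#' For k active subtrees all k(k-1)/2 unordered pairs are formed in
#' canonical order (member sets sorted lexicographically); each pair gets
#' a parent estimate and a priority score. With k = 2 the single forced
#' pair is returned with score `NA` (no context set exists and no choice
#' is made).
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param reps list of L x d subtree representation matrices.
#' @param members list of character vectors of leaf labels, parallel to
#'   `reps`.
#' @return A data frame with columns `left`, `right` (member keys) and
#'   `score`.
#' @export
enumerateCandidates <- function(model, reps, members) {
  stopifnot(length(reps) == length(members), length(reps) >= 2L)
  adReset(enabled = FALSE)
  P <- .wrapParams(model@params)
  res <- .adScorePairs(P, lapply(reps, adLeaf), members)
  data.frame(
    left = vapply(seq_len(nrow(res$pairs)),
                  function(n) .memberKey(members[[res$pairs[n, 1L]]]), ""),
    right = vapply(seq_len(nrow(res$pairs)),
                   function(n) .memberKey(members[[res$pairs[n, 2L]]]), ""),
    score = vapply(res$scores,
                   function(s) if (is.null(s)) NA_real_ else s$val[1L, 1L], 0)
  )
}
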