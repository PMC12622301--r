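# Iterative tree construction from scored candidate pairs. Starting from N
# singleton subtrees, N-2 scored joins are performed (argmax for the greedy
# strategy, temperature softmax sampling for Monte-Carlo search), then the
# final two subtrees are connected by an unscored forced edge, yielding an
# unrooted binary topology. Ties always break to the lowest canonical pair
# index, so construction is exactly reproducible.

#' Temperature-scaled softmax selection probabilities
#'
#' `p_i = exp(s_i / gamma) / sum_j exp(s_j / gamma)`. As `gamma` tends to
#' zero the distribution concentrates on the argmax; large `gamma`
#' flattens it.
#'
#' @param scores numeric vector of candidate priority scores.
#' @param gamma positive sampling temperature.
#' @return A probability vector summing to 1.
#' @export
selectProbabilities <- function(scores, gamma = 1) {
  if (gamma <= 0) stop("gamma must be positive")
  stopifnot(length(scores) >= 1L, all(is.finite(scores)))
  x <- scores / gamma
  e <- exp(x - max(x))
  e / sum(e)
}

# shared construction loop; `chooser(svals)` returns the index of the join
# to execute among the canonically ordered candidates
.constructTree <- function(model, msa, chooser, scoreFn = NULL,
                           gradEnabled = FALSE, gamma = NULL) {
  codes <- msaCodes(msa)
  N <- nrow(codes); L <- ncol(codes)
  if (N < 3L) stop("tree construction needs at least 3 taxa")
  labels <- rownames(codes)

  members <- as.list(labels)
  frags <- labels
  trace <- list()
  logpNodes <- list()

  useNeural <- is.null(scoreFn)
  if (useNeural) {
    adReset(enabled = gradEnabled)
    P <- .wrapParams(model@params)
    hFlat <- .adEncode(P, codes, model@config)
    reps <- lapply(seq_len(N), function(i) {
      adGatherRows(hFlat, ((i - 1L) * L + 1L):(i * L))
    })
  }

  step <- 0L
  while (length(members) > 2L) {
    step <- step + 1L
    k <- length(members)
    if (useNeural) {
      res <- .adScorePairs(P, reps, members)
      svals <- vapply(res$scores, function(s) s$val[1L, 1L], 0)
      pairsIdx <- res$pairs
    } else {
      keys <- vapply(members, .memberKey, "")
      ord <- order(keys)
      pairsIdx <- do.call(rbind, unlist(lapply(seq_len(k - 1L), function(a) {
        lapply((a + 1L):k, function(b) c(ord[a], ord[b]))
      }), recursive = FALSE))
      svals <- vapply(seq_len(nrow(pairsIdx)), function(n) {
        scoreFn(members[[pairsIdx[n, 1L]]], members[[pairsIdx[n, 2L]]])
      }, 0)
    }
    pairKeys <- vapply(seq_len(nrow(pairsIdx)), function(n) {
      paste(.memberKey(members[[pairsIdx[n, 1L]]]),
            .memberKey(members[[pairsIdx[n, 2L]]]), sep = "|")
    }, "")
    sel <- chooser(svals, pairKeys)
    i <- pairsIdx[sel, 1L]; j <- pairsIdx[sel, 2L]
    if (useNeural && gradEnabled && !is.null(gamma)) {
      vec <- adAffine(adRbind(res$scores), 1 / gamma)
      logpNodes[[step]] <- adPick(adLogSoftmaxCol(vec), sel)
    }
    trace[[step]] <- data.frame(
      step = step, left = .memberKey(members[[i]]), right = .memberKey(members[[j]]),
      score = svals[sel]
    )
    newMembers <- c(members[[i]], members[[j]])
    newFrag <- sprintf("(%s,%s)", frags[i], frags[j])
    keep <- setdiff(seq_len(k), c(i, j))
    if (useNeural) {
      reps <- c(reps[keep], list(res$parents[[sel]]))
    }
    members <- c(members[keep], list(newMembers))
    frags <- c(frags[keep], newFrag)
  }
  tree <- parseNewick(sprintf("(%s,%s);", frags[1L], frags[2L]))
  list(
    tree = tree,
    trace = do.call(rbind, trace),
    wrappedParams = if (useNeural) P else NULL,
    logpNodes = logpNodes,
    logProb = if (length(logpNodes)) {
      sum(vapply(logpNodes, function(n) n$val[1L, 1L], 0))
    } else NULL
  )
}

#' Greedy learnable neighbor joining
#'
#' Performs N-2 argmax joins by learned priority score (ties to the lowest
#' canonical pair index) and connects the final two subtrees. The result
#' is a deterministic unrooted binary topology on all N leaves.
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param msa a [PhyloMSA][PhyloMSA-class] with at least 3 taxa.
#' @param scoreFn optional score oracle `function(membersLeft,
#'   membersRight)` that replaces the neural scorer (used e.g. for
#'   oracle-guided construction tests and baselines).
#' @return A list with `tree` (`ape::phylo`, topology only) and `trace`
#'   (data frame: step, left, right, score).
#' @export
greedyBuild <- function(model, msa, scoreFn = NULL) {
  out <- .constructTree(model, msa, chooser = function(svals, keys) which.max(svals),
                        scoreFn = scoreFn)
  out[c("tree", "trace")]
}

#' Stochastic tree construction by temperature sampling
#'
#' At each step the join is sampled from the temperature-scaled softmax of
#' the candidate scores; the log-probability of the realized trajectory
#' (the sum over the N-2 sampled decisions) is returned. As `gamma` tends
#' to 0 the sampled tree coincides with [greedyBuild()].
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param msa a [PhyloMSA][PhyloMSA-class].
#' @param gamma positive sampling temperature.
#' @param seed optional integer seed making the draw reproducible.
#' @return A list with `tree`, `trace`, and `logProb` (<= 0).
#' @export
sampleBuild <- function(model, msa, gamma = 1, seed = NULL) {
  if (gamma <= 0) stop("gamma must be positive")
  if (!is.null(seed)) set.seed(seed)
  logp <- 0
  chooser <- function(svals, keys) {
    p <- selectProbabilities(svals, gamma)
    idx <- sample.int(length(p), 1L, prob = p)
    logp <<- logp + log(p[idx])
    idx
  }
  out <- .constructTree(model, msa, chooser = chooser)
  list(tree = out$tree, trace = out$trace, logProb = logp)
}

#' Likelihood-guided Monte-Carlo tree search
#'
#' Draws `nSamples` trees by [sampleBuild()] in addition to the greedy
#' tree, assigns branch lengths (fixed or optimized), and returns the tree
#' with the highest pruning log-likelihood. Ties prefer the greedy tree,
#' then the earliest sample. The selected log-likelihood is monotone
#' non-decreasing in `nSamples` for a fixed seed.
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param msa a [PhyloMSA][PhyloMSA-class].
#' @param subModel [GTRModel][GTRModel-class] used for the likelihood.
#' @param nSamples number of sampled trees (0 reduces to greedy).
#' @param gamma sampling temperature.
#' @param branchLengthMode `"fixed"` or `"optimize"` (see
#'   [assignBranchLengths()]).
#' @param seed optional integer seed.
#' @return A list with `tree` (with branch lengths), `logLik`, and
#'   `candidates` (data frame of per-tree log-likelihoods; entry 1 is the
#'   greedy tree).
#' @export
mcSearch <- function(model, msa, subModel = jcModel(), nSamples = 32L,
                     gamma = 1, branchLengthMode = c("fixed", "optimize"),
                     seed = NULL) {
  branchLengthMode <- match.arg(branchLengthMode)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  trees <- list(greedyBuild(model, msa)$tree)
  for (s in seq_len(nSamples)) {
    trees[[s + 1L]] <- sampleBuild(model, msa, gamma = gamma, seed = seed + s)$tree
  }
  withBL <- lapply(trees, function(tr) {
    assignBranchLengths(tr, msa, subModel, mode = branchLengthMode)
  })
  ll <- vapply(withBL, function(tr) felsensteinLogLik(tr, msa, subModel), 0)
  best <- which.max(ll)  # first max: greedy wins ties, then earliest sample
  list(tree = withBL[[best]], logLik = ll[best],
       candidates = data.frame(tree = seq_along(ll) - 1L, logLik = ll))
}
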