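# Supervised training with the margin ranking loss and selective negative
# penalization, REINFORCE fine-tuning with likelihood reward, and the
# uniform random-join baseline.
#
# Supervised training teacher-forces the reconstruction of each reference
# tree: at every step all candidate pairs are scored, candidates are
# labeled correct when their merged leaf set is one side of a bipartition
# of the reference tree, the executed join is the canonically smallest
# correct candidate, and the hinge ranking loss is applied between correct
# scores and the top-K scoring incorrect ones. The loss for a sample is
# the mean over its N-2 joining steps; the batch loss is the mean over
# samples. Optimization is Adam with global gradient-norm clipping.

# leaf sets compatible with a reference tree: every side of every edge
# bipartition (including singleton sides) plus the full taxon set
.compatibleSets <- function(tree) {
  taxa <- sort(tree$tip.label)
  keys <- new.env(parent = emptyenv(), hash = TRUE)
  assign(.splitKey(taxa), TRUE, envir = keys)
  for (side in .edgeClades(tree)) {
    assign(.splitKey(side), TRUE, envir = keys)
    assign(.splitKey(setdiff(taxa, side)), TRUE, envir = keys)
  }
  keys
}

.isCompatible <- function(keys, members) {
  exists(.splitKey(members), envir = keys, inherits = FALSE)
}

#' Label candidate joins against a reference tree
#'
#' A candidate pair is correct when the union of its member sets is one
#' side of a bipartition of the reference tree (trivial splits —
#' singletons and their complements — and the full taxon set count as
#' compatible). Candidates are enumerated in canonical order, matching
#' [enumerateCandidates()].
#'
#' @param members list of character vectors: the leaf labels of the
#'   active subtrees.
#' @param refTree reference `ape::phylo` whose tips are exactly the union
#'   of `members`.
#' @return A data frame with columns `left`, `right`, `correct`.
#' @export
labelCandidates <- function(members, refTree) {
  allLeaves <- sort(unlist(members))
  if (!setequal(allLeaves, refTree$tip.label) || anyDuplicated(allLeaves)) {
    stop("subtree members must partition the reference tree's leaf set")
  }
  keys <- .compatibleSets(refTree)
  mk <- vapply(members, .memberKey, "")
  ord <- order(mk)
  k <- length(members)
  rows <- list()
  n <- 0L
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      i <- ord[a]; j <- ord[b]
      n <- n + 1L
      rows[[n]] <- data.frame(
        left = mk[i], right = mk[j],
        correct = .isCompatible(keys, c(members[[i]], members[[j]]))
      )
    }
  }
  do.call(rbind, rows)
}

#' Margin ranking loss for one construction step
#'
#' Hinge loss `mean over (a, b) of max(m - (s_a - s_b), 0)` over pairs of
#' a correct candidate a and a selected incorrect candidate b, where the
#' selected negatives are the `K` highest-scoring incorrect candidates
#' (selective penalization of hard negatives). Zero when there is no
#' correct or no incorrect candidate; zero exactly when every correct
#' score exceeds every selected negative score by at least `m`.
#'
#' @param scores numeric vector of candidate scores.
#' @param correct logical vector parallel to `scores`.
#' @param m positive margin.
#' @param K number of hard negatives kept per step (capped at the number
#'   of negatives).
#' @return A single nonnegative numeric loss.
#' @export
stepRankingLoss <- function(scores, correct, m = 1, K = 4L) {
  stopifnot(length(scores) == length(correct), m > 0, K >= 1L)
  pos <- scores[correct]
  neg <- scores[!correct]
  if (!length(pos) || !length(neg)) return(0)
  negSel <- sort(neg, decreasing = TRUE)[seq_len(min(K, length(neg)))]
  mean(pmax(m - outer(pos, negSel, "-"), 0))
}

# tape version: scoreNodes is a list of 1x1 nodes; returns NULL when the
# step has no positive/negative pair
.adStepLoss <- function(scoreNodes, correct, m, K) {
  posIdx <- which(correct)
  negIdx <- which(!correct)
  if (!length(posIdx) || !length(negIdx)) return(NULL)
  negVals <- vapply(scoreNodes[negIdx], function(s) s$val[1L, 1L], 0)
  keep <- negIdx[order(negVals, decreasing = TRUE)[seq_len(min(K, length(negIdx)))]]
  hinges <- list()
  n <- 0L
  for (a in posIdx) {
    for (b in keep) {
      n <- n + 1L
      hinges[[n]] <- adRelu(adAffine(adSub(scoreNodes[[a]], scoreNodes[[b]]), -1, m))
    }
  }
  adMeanAll(adRbind(hinges))
}

# teacher-forced loss node for one (msa, refTree) sample; params already
# wrapped on the current tape
.adSupervisedSample <- function(P, cfg, msa, refTree, m, K) {
  codes <- msaCodes(msa)
  N <- nrow(codes); L <- ncol(codes)
  keys <- .compatibleSets(refTree)
  hFlat <- .adEncode(P, codes, cfg)
  reps <- lapply(seq_len(N), function(i) {
    adGatherRows(hFlat, ((i - 1L) * L + 1L):(i * L))
  })
  members <- as.list(rownames(codes))
  stepLosses <- list()
  while (length(members) > 2L) {
    res <- .adScorePairs(P, reps, members)
    correct <- vapply(seq_len(nrow(res$pairs)), function(n) {
      .isCompatible(keys, c(members[[res$pairs[n, 1L]]], members[[res$pairs[n, 2L]]]))
    }, TRUE)
    if (!any(correct)) {
      stop("no reference-compatible candidate; construction left the reference tree")
    }
    loss <- .adStepLoss(res$scores, correct, m, K)
    if (!is.null(loss)) stepLosses[[length(stepLosses) + 1L]] <- loss
    sel <- which(correct)[1L]  # canonically smallest correct pair
    i <- res$pairs[sel, 1L]; j <- res$pairs[sel, 2L]
    keep <- setdiff(seq_along(members), c(i, j))
    reps <- c(reps[keep], list(res$parents[[sel]]))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
  }
  if (!length(stepLosses)) return(NULL)
  adAffine(adRbind(stepLosses), 1 / (N - 2L))  # sum later via adSumAll
}

# ---- Adam optimizer -----------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 1) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(gnorm) && gnorm > clip && gnorm > 0) {
    grads <- lapply(grads, function(g) g * (clip / gnorm))
  }
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state, gradNorm = gnorm)
}

.collectGrads <- function(P) {
  lapply(P, function(node) {
    if (is.null(node$grad)) node$val * 0 else node$grad
  })
}

#' Mean normalized RF of greedy construction over a set of pairs
#'
#' Convenience evaluation helper: runs [greedyBuild()] on each pair and
#' averages the normalized Robinson-Foulds distance to the reference
#' trees.
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class].
#' @param pairs list of `list(tree, msa)` elements (as produced by
#'   [simulateDataset()]).
#' @return Mean normalized RF (numeric scalar).
#' @export
evaluateMeanRF <- function(model, pairs) {
  mean(vapply(pairs, function(p) {
    rfDistance(greedyBuild(model, p$msa)$tree, p$tree)$normalized
  }, 0))
}

#' Supervised training with the margin ranking loss
#'
#' Teacher-forced training over simulated (tree, MSA) pairs. Each epoch
#' shuffles the training pairs into batches; the batch loss is the mean
#' over samples of the per-sample mean step ranking loss, minimized by
#' Adam with gradient-norm clipping. When validation pairs are given, the
#' mean normalized RF of greedy construction is checked once per epoch
#' and training stops early after `patience` consecutive checks without
#' improvement; the best-validation weights are returned.
#'
#' @param model a [NeuralNJModel][NeuralNJModel-class] to start from.
#' @param trainPairs,valPairs lists of `list(tree, msa)` elements
#'   (`valPairs` may be NULL to disable early stopping).
#' @param margin ranking margin m.
#' @param negativesPerPositive hard negatives kept per step (K).
#' @param lr Adam learning rate.
#' @param batchSize samples per gradient step.
#' @param epochs maximum epochs.
#' @param patience consecutive validation checks without improvement
#'   before stopping.
#' @param clip global gradient-norm clip.
#' @param seed optional seed controlling shuffling.
#' @return A list with `model` (trained), `history` (data frame: epoch,
#'   trainLoss, valRF).
#' @export
trainSupervised <- function(model, trainPairs, valPairs = NULL, margin = 1,
                            negativesPerPositive = 4L, lr = 1e-3,
                            batchSize = 8L, epochs = 3L, patience = 5L,
                            clip = 1, seed = NULL) {
  stopifnot(length(trainPairs) >= 1L, patience >= 1L, margin > 0)
  if (!is.null(seed)) set.seed(seed)
  params <- model@params
  cfg <- model@config
  state <- .adamInit(params)
  history <- list()
  bestRF <- Inf; bestParams <- params; checksSinceBest <- 0L
  for (epoch in seq_len(epochs)) {
    idx <- sample(length(trainPairs))
    batches <- split(idx, ceiling(seq_along(idx) / batchSize))
    epochLosses <- c()
    for (batch in batches) {
      gradSum <- NULL
      batchLoss <- 0
      for (s in batch) {
        adReset(enabled = TRUE)
        P <- .wrapParams(params)
        lossVec <- .adSupervisedSample(P, cfg, trainPairs[[s]]$msa,
                                       trainPairs[[s]]$tree,
                                       margin, negativesPerPositive)
        if (is.null(lossVec)) next
        loss <- adSumAll(lossVec)
        batchLoss <- batchLoss + loss$val[1L, 1L]
        adBackward(loss)
        g <- .collectGrads(P)
        gradSum <- if (is.null(gradSum)) g else Map(`+`, gradSum, g)
      }
      if (is.null(gradSum)) next
      grads <- lapply(gradSum, function(g) g / length(batch))
      upd <- .adamStep(params, grads, state, lr = lr, clip = clip)
      params <- upd$params; state <- upd$state
      epochLosses <- c(epochLosses, batchLoss / length(batch))
    }
    valRF <- NA_real_
    if (!is.null(valPairs)) {
      valModel <- new("NeuralNJModel", config = cfg, params = params)
      valRF <- evaluateMeanRF(valModel, valPairs)
      if (valRF < bestRF - 1e-9) {
        bestRF <- valRF; bestParams <- params; checksSinceBest <- 0L
      } else {
        checksSinceBest <- checksSinceBest + 1L
      }
    }
    history[[epoch]] <- data.frame(epoch = epoch, trainLoss = mean(epochLosses),
                                   valRF = valRF)
    if (!is.null(valPairs) && checksSinceBest >= patience) break
  }
  finalParams <- if (!is.null(valPairs)) bestParams else params
  list(model = new("NeuralNJModel", config = cfg, params = finalParams),
       history = do.call(rbind, history))
}

#' REINFORCE fine-tuning with likelihood reward
#'
#' Adapts the model to a single target alignment. Per epoch, M
#' trajectories are sampled by temperature softmax; each complete
#' topology receives branch lengths (fixed by default) and its pruning
#' log-likelihood as reward R. The policy gradient of
#' `-(1/M) sum_i log p(tau_i | theta) (R_i - b)` is applied with Adam,
#' where the baseline b is the previous epoch's mean reward (the current
#' batch mean in the first epoch, which centers the advantages exactly).
#' The highest-reward tree ever sampled is tracked and returned.
#'
#' @param model a trained [NeuralNJModel][NeuralNJModel-class].
#' @param msa the target [PhyloMSA][PhyloMSA-class].
#' @param subModel [GTRModel][GTRModel-class] for the likelihood reward.
#' @param nTrajectories trajectories per epoch (M).
#' @param epochs number of policy-gradient epochs.
#' @param gamma sampling temperature.
#' @param lr Adam learning rate.
#' @param branchLengthMode `"fixed"` or `"optimize"` for reward branch
#'   lengths.
#' @param clip global gradient-norm clip.
#' @param seed optional integer seed.
#' @param rewardFn optional override `function(tree)` returning the reward
#'   (defaults to the pruning log-likelihood after branch-length
#'   assignment).
#' @return A list with `model` (fine-tuned), `bestTree`, `bestReward`,
#'   and `history` (epoch, meanReward, baseline, gradNorm).
#' @export
reinforceFinetune <- function(model, msa, subModel = jcModel(),
                              nTrajectories = 8L, epochs = 5L, gamma = 1,
                              lr = 1e-3, branchLengthMode = c("fixed", "optimize"),
                              clip = 1, seed = NULL, rewardFn = NULL) {
  branchLengthMode <- match.arg(branchLengthMode)
  stopifnot(nTrajectories >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rewardFn)) {
    rewardFn <- function(tree) {
      felsensteinLogLik(assignBranchLengths(tree, msa, subModel,
                                            mode = branchLengthMode),
                        msa, subModel)
    }
  }
  params <- model@params
  cfg <- model@config
  state <- .adamInit(params)
  b <- NULL
  bestReward <- -Inf; bestTree <- NULL
  history <- list()
  for (epoch in seq_len(epochs)) {
    cur <- new("NeuralNJModel", config = cfg, params = params)
    # rollout pass (no gradients): record the join sequence of each trajectory
    rollouts <- lapply(seq_len(nTrajectories), function(i) {
      out <- sampleBuild(cur, msa, gamma = gamma)
      reward <- rewardFn(out$tree)
      list(keys = paste(out$trace$left, out$trace$right, sep = "|"),
           tree = out$tree, reward = reward)
    })
    rewards <- vapply(rollouts, `[[`, 0, "reward")
    if (max(rewards) > bestReward) {
      bestReward <- max(rewards)
      bestTree <- rollouts[[which.max(rewards)]]$tree
    }
    baseline <- if (is.null(b)) mean(rewards) else b
    adv <- rewards - baseline
    # replay pass: teacher-force each recorded trajectory on the tape and
    # accumulate the policy gradient
    gradSum <- NULL
    for (i in seq_len(nTrajectories)) {
      if (adv[i] == 0) next
      stepCounter <- 0L
      recorded <- rollouts[[i]]$keys
      chooser <- function(svals, keys) {
        stepCounter <<- stepCounter + 1L
        match(recorded[stepCounter], keys)
      }
      out <- .constructTree(cur, msa, chooser = chooser,
                            gradEnabled = TRUE, gamma = gamma)
      logp <- adSumAll(adRbind(out$logpNodes))
      loss <- adAffine(logp, -adv[i] / nTrajectories)
      adBackward(loss)
      g <- .collectGrads(out$wrappedParams)
      gradSum <- if (is.null(gradSum)) g else Map(`+`, gradSum, g)
    }
    gradNorm <- 0
    if (!is.null(gradSum)) {
      upd <- .adamStep(params, gradSum, state, lr = lr, clip = clip)
      params <- upd$params; state <- upd$state; gradNorm <- upd$gradNorm
    }
    b <- mean(rewards)
    history[[epoch]] <- data.frame(epoch = epoch, meanReward = mean(rewards),
                                   baseline = baseline, gradNorm = gradNorm)
  }
  list(model = new("NeuralNJModel", config = cfg, params = params),
       bestTree = bestTree, bestReward = bestReward,
       history = do.call(rbind, history))
}

#' Uniform random-join baseline
#'
#' Builds a topology by choosing a uniformly random candidate pair at
#' every step — the no-information reference against which learned
#' construction is compared.
#'
#' @param msa a [PhyloMSA][PhyloMSA-class].
#' @param seed optional integer seed.
#' @return An unrooted `ape::phylo` topology.
#' @export
randomJoinBaseline <- function(msa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- .constructTree(NULL, msa,
                        chooser = function(svals, keys) sample.int(length(svals), 1L),
                        scoreFn = function(l, r) 0)
  out$tree
}
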