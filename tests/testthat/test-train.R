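test_that("candidate labeling agrees with the reference bipartitions", {
  ref <- parseNewick("((A,B),(C,D));")
  singles <- list("A", "B", "C", "D")
  lab <- labelCandidates(singles, ref)
  expect_equal(nrow(lab), 6L)
  good <- lab[lab$correct, ]
  expect_setequal(paste(good$left, good$right), c("A B", "C D"))

  # final step: the single candidate (union = all taxa) is always correct
  lab2 <- labelCandidates(list(c("A", "B"), c("C", "D")), ref)
  expect_true(lab2$correct)

  expect_error(labelCandidates(list("A", "B"), ref), "partition")

  # following the reference always leaves a correct candidate available
  set.seed(71)
  for (rep in 1:10) {
    ref <- sampleTopology(sample(5:12, 1))
    members <- as.list(ref$tip.label)
    while (length(members) > 2L) {
      lab <- labelCandidates(members, ref)
      expect_true(any(lab$correct))
      hit <- which(lab$correct)[1]
      l <- strsplit(lab$left[hit], ",")[[1]]
      r <- strsplit(lab$right[hit], ",")[[1]]
      il <- which(vapply(members, function(m) setequal(m, l), TRUE))[1]
      ir <- which(vapply(members, function(m) setequal(m, r), TRUE))[1]
      members <- c(members[-c(il, ir)], list(c(l, r)))
    }
  }
})

test_that("the step ranking loss is the averaged hinge over hard negatives", {
  expect_equal(stepRankingLoss(c(2, 0), c(TRUE, FALSE), m = 1), 0)
  expect_equal(stepRankingLoss(c(0.5, 0), c(TRUE, FALSE), m = 1), 0.5)
  expect_equal(stepRankingLoss(c(1.5, 0.2, 0), c(TRUE, TRUE, FALSE), m = 1), 0.4)
  # no positives or no negatives: zero loss
  expect_equal(stepRankingLoss(c(1, 2), c(TRUE, TRUE), m = 1), 0)
  expect_equal(stepRankingLoss(c(1, 2), c(FALSE, FALSE), m = 1), 0)
  # selective penalization keeps only the K highest-scoring negatives
  expect_equal(stepRankingLoss(c(1, 0.9, -5, -9), c(TRUE, FALSE, FALSE, FALSE),
                               m = 1, K = 1L), 0.9)
  expect_gte(stepRankingLoss(rnorm(6), c(TRUE, TRUE, rep(FALSE, 4))), 0)
})

test_that("zero loss with full negative coverage implies a correct argmax", {
  set.seed(72)
  hits <- 0L
  for (rep in 1:1000) {
    k <- sample(3:12, 1)
    correct <- rep(FALSE, k)
    correct[sample(k, sample(1:(k - 1), 1))] <- TRUE
    scores <- rnorm(k)
    if (rep %% 2 == 0) {
      # construct margin-satisfying instances so the implication is exercised
      scores[correct] <- scores[correct] + max(scores[!correct]) -
        min(scores[correct]) + 1 + runif(1)
    }
    loss <- stepRankingLoss(scores, correct, m = 1, K = k)
    if (loss == 0 && any(correct) && any(!correct)) {
      hits <- hits + 1L
      expect_true(correct[which.max(scores)])
    }
  }
  expect_gt(hits, 300L)  # the implication was actually tested
})

test_that("backpropagated training gradients match finite differences", {
  set.seed(73)
  mod <- tinyModel()
  pair <- simPair(8, 32)
  lossOf <- function(params) {
    learnNJ:::adReset(TRUE)
    P <- learnNJ:::.wrapParams(params)
    lv <- learnNJ:::.adSupervisedSample(P, mod@config, pair$msa, pair$tree, 1, 4L)
    learnNJ:::adSumAll(lv)
  }
  loss <- lossOf(mod@params)
  learnNJ:::adReset(TRUE)
  P <- learnNJ:::.wrapParams(mod@params)
  lv <- learnNJ:::.adSupervisedSample(P, mod@config, pair$msa, pair$tree, 1, 4L)
  learnNJ:::adBackward(learnNJ:::adSumAll(lv))
  for (nm in c("embed.W", "layer1.row.Wq.1", "layer1.col.Wk.2",
               "dec.gate1.W", "dec.ctx.Wq", "dec.eval.W1")) {
    g <- P[[nm]]$grad
    idx <- which(abs(g) == max(abs(g)), arr.ind = TRUE)[1, ]
    eps <- 1e-5
    up <- mod@params; up[[nm]][idx[1], idx[2]] <- up[[nm]][idx[1], idx[2]] + eps
    dn <- mod@params; dn[[nm]][idx[1], idx[2]] <- dn[[nm]][idx[1], idx[2]] - eps
    fd <- (lossOf(up)$val[1, 1] - lossOf(dn)$val[1, 1]) / (2 * eps)
    expect_lt(abs(g[idx[1], idx[2]] - fd) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("supervised training reduces the ranking loss on a tiny dataset", {
  set.seed(74)
  pairs <- simulateDataset(data.frame(nTaxa = 8L, seqLength = 64L, count = 30L),
                           seed = 101, model = "jc")$pairs
  mod <- tinyModel(seed = 7)
  res <- trainSupervised(mod, pairs, valPairs = NULL, epochs = 3L,
                         batchSize = 8L, seed = 1)
  expect_equal(nrow(res$history), 3L)
  expect_lt(res$history$trainLoss[3], res$history$trainLoss[1])
  expect_s4_class(res$model, "NeuralNJModel")
})

test_that("early stopping honors the patience contract", {
  set.seed(75)
  pairs <- simulateDataset(data.frame(nTaxa = 6L, seqLength = 32L, count = 8L),
                           seed = 55, model = "jc")$pairs
  mod <- tinyModel(seed = 3)
  res <- trainSupervised(mod, pairs[1:6], valPairs = pairs[7:8], epochs = 8L,
                         batchSize = 4L, patience = 2L, seed = 2)
  h <- res$history
  best <- which.min(h$valRF)
  # training never continues more than `patience` checks past the best
  expect_lte(nrow(h), best + 2L)
})

test_that("REINFORCE centers advantages and is inert under constant reward", {
  set.seed(76)
  mod <- tinyModel()
  pair <- simPair(6, 24)
  const <- reinforceFinetune(mod, pair$msa, nTrajectories = 4L, epochs = 2L,
                             seed = 5, rewardFn = function(tree) 3.14)
  expect_true(all(mapply(function(a, b) isTRUE(all.equal(a, b)),
                         mod@params, const$model@params)))
  expect_equal(const$history$gradNorm, c(0, 0))
  # first-epoch baseline is the batch mean (advantages sum to zero)
  rl <- reinforceFinetune(mod, pair$msa, nTrajectories = 4L, epochs = 3L,
                          seed = 5)
  expect_equal(rl$history$baseline[1], rl$history$meanReward[1])
  # subsequent baselines are the previous epoch's mean reward
  expect_equal(rl$history$baseline[-1],
               rl$history$meanReward[-nrow(rl$history)])
  # the best tree/reward tracks the running maximum
  expect_gte(rl$bestReward, max(rl$history$meanReward))
  expect_s3_class(rl$bestTree, "phylo")
})
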