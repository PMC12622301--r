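test_that("topology sampling is uniform over labeled binary topologies", {
  set.seed(1)
  t3 <- sampleTopology(3)
  expect_equal(length(t3$tip.label), 3L)
  expect_equal(t3$Nnode, 1L)
  expect_error(sampleTopology(2), "at least 3")

  # leaf and internal node counts (unrooted: n - 2 internal nodes)
  for (n in c(5, 12, 40)) {
    tr <- sampleTopology(n)
    expect_equal(length(tr$tip.label), n)
    expect_equal(tr$Nnode, n - 2L)
  }

  # n = 4: each of the 3 quartet topologies with frequency 1/3
  quartetClass <- function(tr) {
    s <- treeBipartitions(tr)[[1]]
    paste(s, collapse = "")
  }
  cls <- replicate(3000, quartetClass(sampleTopology(4)))
  counts <- table(cls)
  expect_length(counts, 3L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("branch lengths are exponential with the drawn per-tree rate", {
  set.seed(2)
  big <- sampleTopology(600)  # 2 * 600 - 3 branches per draw
  lens <- unlist(lapply(1:9, function(i) sampleBranchLengths(big, 5)$edge.length))
  expect_gt(length(lens), 10000)
  se <- 0.2 / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 0.2), 3 * se)
  expect_true(all(lens > 0))

  lambdas <- replicate(500, sampleLambda())
  expect_true(all(lambdas >= 2 & lambdas <= 5))
  # log-uniform: median at sqrt(10) = geometric mean of the bounds
  expect_lt(abs(stats::median(log(lambdas)) - mean(log(c(2, 5)))), 0.1)
})

test_that("sampled GTR parameters define valid normalized generators", {
  set.seed(3)
  for (rep in 1:25) {
    m <- sampleGTRModel()
    expect_lt(abs(sum(m@baseFreqs) - 1), 1e-12)
    expect_true(m@gammaShape >= 0.2 && m@gammaShape <= 5)
    rm <- gtrRateMatrix(m)
    expect_lt(max(abs(rowSums(rm$Q))), 1e-12)          # rows sum to 0
    expect_lt(max(abs(rm$pi %*% rm$Q)), 1e-12)         # stationarity
    expect_lt(abs(-sum(rm$pi * diag(rm$Q)) - 1), 1e-12) # unit mean rate
    # detailed balance (reversibility)
    db <- outer(rm$pi, rep(1, 4)) * rm$Q
    expect_lt(max(abs(db - t(db))), 1e-12)
  }
  jc <- jcModel()
  qjc <- gtrRateMatrix(jc)$Q
  expect_equal(unname(qjc[1, 2]), 1 / 3, tolerance = 1e-12)
  expect_equal(gammaCategoryRates(jc), 1)
})

test_that("sequence evolution follows the substitution process", {
  set.seed(4)
  tr <- sampleTopology(6)
  tr$edge.length <- rep(0, nrow(tr$edge))
  m0 <- evolveSequences(tr, jcModel(), 40)
  seqs <- msaSequences(m0)
  expect_true(all(seqs == seqs[[1]]))  # no substitutions at zero lengths

  mInv <- gtrModel(gammaShape = 1, pInv = 1)
  codes <- msaCodes(evolveSequences(rTreeWithLengths(5, 1), mInv, 50))
  expect_true(all(apply(codes, 2, function(col) length(unique(col)) == 1L)))

  expect_error(evolveSequences(sampleTopology(4), jcModel(), 10), "branch lengths")

  # JC closed form for the two-taxon divergence at total path t
  t <- 0.3
  L <- 50000
  msa2 <- evolveSequences(parseNewick("(A:0.15,B:0.15);"), jcModel(), L)
  pObs <- mean(msaCodes(msa2)[1, ] != msaCodes(msa2)[2, ])
  pExp <- 0.75 * (1 - exp(-4 * t / 3))
  expect_lt(abs(pObs - pExp), 3 * sqrt(pExp * (1 - pExp) / L))
})

test_that("deletion events produce bounded, monotone gap ratios", {
  set.seed(6)
  pair <- simPair(8, 200)
  expect_identical(applyDeletions(pair$msa, 0), pair$msa)
  ratios <- vapply(c(0, 0.01, 0.03, 0.08), function(r) {
    mean(replicate(20, gapRatio(applyDeletions(pair$msa, r))))
  }, 0)
  expect_true(all(diff(ratios) > 0))
  expect_lt(max(vapply(1:20, function(i) {
    gapRatio(applyDeletions(pair$msa, 0.03))
  }, 0)), 0.3)
})

test_that("dataset generation is reproducible and manifests match the design", {
  man <- data.frame(nTaxa = 5L, seqLength = 30L, count = 3L)
  d1 <- simulateDataset(man, seed = 77)
  d2 <- simulateDataset(man, seed = 77)
  expect_equal(d1$summary$totalPairs, 3L)
  for (i in 1:3) {
    expect_identical(msaCodes(d1$pairs[[i]]$msa), msaCodes(d2$pairs[[i]]$msa))
    expect_identical(writeNewick(d1$pairs[[i]]$tree), writeNewick(d2$pairs[[i]]$tree))
    expect_true(d1$pairs[[i]]$meta$lambda >= 2 && d1$pairs[[i]]$meta$lambda <= 5)
  }
  d3 <- simulateDataset(man, seed = 78)
  expect_false(identical(msaCodes(d1$pairs[[1]]$msa), msaCodes(d3$pairs[[1]]$msa)))

  # file output mode writes one Newick + FASTA per pair plus a manifest
  dir <- withr::local_tempdir()
  simulateDataset(man, seed = 77, dir = dir)
  expect_length(list.files(dir, pattern = "\\.nwk$"), 3L)
  expect_length(list.files(dir, pattern = "\\.fasta$"), 3L)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))

  # the paper-scale designs: 29 lengths x 1000 = 29,000 and 128 x 5 = 640
  expect_equal(sum(trainingManifest()$count), 29000L)
  expect_equal(nrow(trainingManifest()), 29L)
  expect_equal(sum(testManifest()$count), 640L)
})

test_that("long simulated sequences converge to the stationary composition", {
  set.seed(8)
  m <- gtrModel(rates = c(1.5, 3, 0.5, 0.9, 2.8, 1),
                baseFreqs = c(0.4, 0.3, 0.2, 0.1), gammaShape = 0.8, pInv = 0.2)
  L <- 40000
  msa <- evolveSequences(parseNewick("(A:0.5,B:0.5);"), m, L)
  freq <- tabulate(msaCodes(msa)[1, ] + 1L, 5L)[1:4] / L
  for (x in 1:4) {
    se <- sqrt(m@baseFreqs[x] * (1 - m@baseFreqs[x]) / L)
    expect_lt(abs(freq[x] - m@baseFreqs[x]), 4 * se)
  }
})
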