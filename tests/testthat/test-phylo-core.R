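test_that("Newick parsing and writing round-trip topology and lengths", {
  tr <- parseNewick("(A:1,B:1);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))

  q <- parseNewick("((A,B),(C,D));")
  expect_equal(length(treeBipartitions(q)), 1L)
  expect_equal(treeBipartitions(q)[[1]], c("A", "B"))

  expect_error(parseNewick("((A,B),(C,D);"), "unbalanced")
  expect_error(parseNewick("((A,B),(A,C));"), "duplicate")

  # no-lengths tree has no ':' tokens
  topo <- sampleTopology(6)
  expect_false(grepl(":", writeNewick(topo), fixed = TRUE))

  # round trip preserves the bipartition set for random trees
  set.seed(31)
  for (rep in 1:10) {
    tr <- rTreeWithLengths(sample(4:20, 1))
    back <- parseNewick(writeNewick(tr))
    expect_equal(rfDistance(tr, back)$raw, 0L)
    expect_equal(back$edge.length[order(back$edge[, 2])][1:3] >= 0, rep(TRUE, 3))
  }
})

test_that("bipartition counts follow the N-3 law", {
  expect_length(treeBipartitions(parseNewick("((A,B),C);")), 0L)
  set.seed(7)
  for (n in c(4, 7, 10, 25)) {
    expect_length(treeBipartitions(sampleTopology(n)), n - 3L)
  }
})

test_that("Robinson-Foulds distance matches the bipartition definition", {
  t1 <- parseNewick("((A,B),(C,D));")
  t2 <- parseNewick("((A,C),(B,D));")
  expect_equal(rfDistance(t1, t1), list(raw = 0L, normalized = 0))
  r <- rfDistance(t1, t2)
  expect_equal(r$raw, 2L)
  expect_equal(r$normalized, 1)

  # one NNI on a 5-leaf caterpillar: 2 raw, 0.5 normalized
  c1 <- parseNewick("((((A,B),C),D),E);")
  c2 <- parseNewick("((((A,B),D),C),E);")
  expect_equal(rfDistance(c1, c2), list(raw = 2L, normalized = 0.5))

  # symmetry, identity, range on random trees; phangorn as cross-check
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(5:15, 1)
    a <- sampleTopology(n)
    b <- sampleTopology(n)
    r1 <- rfDistance(a, b)
    expect_identical(r1, rfDistance(b, a))
    expect_gte(r1$normalized, 0)
    expect_lte(r1$normalized, 1)
    expect_equal(r1$raw, as.integer(phangorn::RF.dist(a, b)))
  }
  expect_error(rfDistance(parseNewick("((A,B),(C,E));"), t2), "leaf sets differ")
})

test_that("patristic distances are path sums satisfying the four-point condition", {
  expect_equal(patristicDistances(parseNewick("(A:0.3,B:0.2);"))["A", "B"], 0.5)
  tr <- sampleTopology(5)
  tr$edge.length <- rep(0, nrow(tr$edge))
  expect_true(all(patristicDistances(tr) == 0))
  expect_error(patristicDistances(sampleTopology(5)), "branch length")

  set.seed(3)
  tr <- rTreeWithLengths(8)
  d <- patristicDistances(tr)
  labs <- rownames(d)
  combos <- utils::combn(labs, 4)
  for (k in seq_len(ncol(combos))) {
    q <- combos[, k]
    sums <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                   d[q[1], q[3]] + d[q[2], q[4]],
                   d[q[1], q[4]] + d[q[2], q[3]]))
    expect_equal(sums[2], sums[3], tolerance = 1e-9)
  }
})

test_that("neighbor joining recovers additive trees and matches ape", {
  tr3 <- neighborJoining(matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
                                dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  expect_setequal(tr3$tip.label, c("A", "B", "C"))

  labs <- c("A", "B", "C", "D")
  dm <- matrix(4, 4, 4, dimnames = list(labs, labs))
  dm[cbind(labs, labs)] <- 0
  dm["A", "B"] <- dm["B", "A"] <- 2
  dm["C", "D"] <- dm["D", "C"] <- 2
  got <- neighborJoining(dm)
  expect_equal(rfDistance(got, parseNewick("((A,B),(C,D));"))$raw, 0L)

  expect_error(neighborJoining(dm[1:2, 1:2]), "at least 3")

  # consistency on additive inputs; ape::nj as independent cross-check
  set.seed(19)
  for (rep in 1:10) {
    tr <- rTreeWithLengths(sample(5:30, 1))
    d <- patristicDistances(tr)
    ours <- neighborJoining(d)
    expect_equal(rfDistance(ours, tr)$normalized, 0)
    expect_equal(rfDistance(ours, ape::nj(as.dist(d)))$normalized, 0)
    # estimated branch lengths reproduce the additive distances
    expect_equal(patristicDistances(ours)[rownames(d), colnames(d)], d,
                 tolerance = 1e-6)
  }
})

test_that("distance matrices round-trip through tab-separated text", {
  set.seed(37)
  tr <- rTreeWithLengths(7)
  d <- patristicDistances(tr)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceMatrix(d, f)
  back <- readDistanceMatrix(f)
  expect_equal(back, d, tolerance = 1e-9)
  expect_equal(rfDistance(neighborJoining(back), tr)$normalized, 0)
})
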