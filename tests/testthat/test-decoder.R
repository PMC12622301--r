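test_that("child fusion is a strict gated convex combination", {
  set.seed(51)
  mod <- tinyModel()
  L <- 6L; d <- mod@config$dModel
  v <- matrix(rnorm(L * d), L, d)
  same <- fuseChildren(mod, v, v)
  expect_equal(same$hTilde, v, tolerance = 1e-12)

  zeroMod <- mod
  zeroMod@params[["dec.gate1.W"]][] <- 0
  zeroMod@params[["dec.gate1.b"]][] <- 0
  hl <- matrix(rnorm(L * d), L, d); hr <- matrix(rnorm(L * d), L, d)
  out0 <- fuseChildren(zeroMod, hl, hr)
  expect_true(all(out0$z == 0.5))
  expect_equal(out0$hTilde, (hl + hr) / 2, tolerance = 1e-12)

  for (rep in 1:50) {
    hl <- matrix(rnorm(L * d), L, d); hr <- matrix(rnorm(L * d), L, d)
    out <- fuseChildren(mod, hl, hr)
    expect_true(all(out$z > 0 & out$z < 1))
    expect_true(all(out$hTilde >= pmin(hl, hr) - 1e-12 &
                      out$hTilde <= pmax(hl, hr) + 1e-12))
  }
})

test_that("ancestral context is order-invariant over the other subtrees", {
  set.seed(52)
  mod <- tinyModel()
  L <- 5L; d <- mod@config$dModel
  ht <- matrix(rnorm(L * d), L, d)
  others <- lapply(1:4, function(i) matrix(rnorm(L * d), L, d))
  a <- ancestralContext(mod, ht, others)
  b <- ancestralContext(mod, ht, others[c(3, 1, 4, 2)])
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(dim(a), c(L, d))

  # all-identical others collapse to the singleton result
  single <- ancestralContext(mod, ht, others[1])
  dup <- ancestralContext(mod, ht, others[c(1, 1, 1)])
  expect_equal(dup, single, tolerance = 1e-12)
  expect_error(ancestralContext(mod, ht, list()), "at least one")
})

test_that("context integration is a gated convex combination", {
  set.seed(53)
  mod <- tinyModel()
  L <- 5L; d <- mod@config$dModel
  v <- matrix(rnorm(L * d), L, d)
  expect_equal(integrateContext(mod, v, v)$hX, v, tolerance = 1e-12)
  for (rep in 1:20) {
    ht <- matrix(rnorm(L * d), L, d); hrest <- matrix(rnorm(L * d), L, d)
    out <- integrateContext(mod, ht, hrest)
    expect_true(all(out$w > 0 & out$w < 1))
    expect_true(all(out$hX >= pmin(ht, hrest) - 1e-12 &
                      out$hX <= pmax(ht, hrest) + 1e-12))
  }
})

test_that("the evaluator averages per-site scores", {
  set.seed(54)
  mod <- tinyModel()
  d <- mod@config$dModel
  hx <- matrix(rnorm(7 * d), 7, d)
  s <- scoreSubtree(mod, hx)
  expect_length(s, 1L)
  # site permutation invariance
  expect_equal(scoreSubtree(mod, hx[sample(7), , drop = FALSE]), s,
               tolerance = 1e-12)
  # single site: score equals the per-site value; mean over duplicated rows
  one <- hx[3, , drop = FALSE]
  expect_equal(scoreSubtree(mod, one[c(1, 1, 1), , drop = FALSE]),
               scoreSubtree(mod, one), tolerance = 1e-12)
})

test_that("candidate enumeration is complete, canonical and order-symmetric", {
  set.seed(55)
  mod <- tinyModel()
  L <- 4L; d <- mod@config$dModel
  mk <- function(k) {
    list(reps = lapply(seq_len(k), function(i) matrix(rnorm(L * d), L, d)),
         members = lapply(seq_len(k), function(i) paste0("t", i)))
  }
  x4 <- mk(4)
  cand <- enumerateCandidates(mod, x4$reps, x4$members)
  expect_equal(nrow(cand), 6L)
  expect_true(all(is.finite(cand$score)))
  # canonical ordering puts the lexicographically smaller member set left
  expect_true(all(cand$left < cand$right))

  # scores do not depend on the order the subtrees are presented in
  perm <- c(4, 2, 1, 3)
  cand2 <- enumerateCandidates(mod, x4$reps[perm], x4$members[perm])
  key <- function(df) paste(df$left, df$right, sep = "|")
  expect_equal(cand2$score[match(key(cand), key(cand2))], cand$score,
               tolerance = 1e-12)

  x12 <- mk(12)
  expect_equal(nrow(enumerateCandidates(mod, x12$reps, x12$members)), 66L)

  # forced final pair: no score
  x2 <- mk(2)
  c2 <- enumerateCandidates(mod, x2$reps, x2$members)
  expect_equal(nrow(c2), 1L)
  expect_true(is.na(c2$score))
})
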