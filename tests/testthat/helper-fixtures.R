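# Shared fixtures: all data is generated in code at test time.

rTreeWithLengths <- function(n, lambda = 3) {
  sampleBranchLengths(sampleTopology(n), lambda)
}

simPair <- function(n, L, model = jcModel(), lambda = 3) {
  tree <- rTreeWithLengths(n, lambda)
  list(tree = tree, msa = evolveSequences(tree, model, L))
}

tinyModel <- function(d = 8L, seed = 42L) {
  neuralNJModel(dModel = d, nLayers = 1L, nHeads = 2L, hiddenMult = 2L,
                maxLen = 256L, seed = seed)
}

# score oracle: 1 when the merged pair is compatible with the reference tree
oracleScorer <- function(refTree) {
  keys <- learnNJ:::.compatibleSets(refTree)
  function(l, r) as.numeric(learnNJ:::.isCompatible(keys, c(l, r)))
}

randomCodesMSA <- function(n, L, labels = paste0("t", seq_len(n))) {
  codes <- matrix(sample(0:3, n * L, replace = TRUE), n, L,
                  dimnames = list(labels, NULL))
  new("PhyloMSA", codes = codes)
}

# independent likelihood oracle: exhaustive sum over internal-node state
# assignments, with the same I+G mixture semantics as the pruning version
bruteForceLogLik <- function(tree, msa, model) {
  rm <- gtrRateMatrix(model)
  rates <- gammaCategoryRates(model)
  codes <- msaCodes(msa)[tree$tip.label, , drop = FALSE]
  nt <- nrow(codes)
  nn <- nt + tree$Nnode
  edges <- tree$edge
  bl <- tree$edge.length
  total <- 0
  for (s in seq_len(ncol(codes))) {
    inv <- 0
    for (x in 1:4) if (all(codes[, s] %in% c(x - 1, 4))) inv <- inv + rm$pi[x]
    gam <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(edges)), function(e) transitionProbs(rm, bl[e] * r))
      nInt <- tree$Nnode
      sumL <- 0
      for (assign in 0:(4^nInt - 1)) {
        st <- integer(nn)
        a <- assign
        for (v in seq_len(nInt)) {
          st[nt + v] <- a %% 4 + 1
          a <- a %/% 4
        }
        p <- rm$pi[st[nt + 1]]
        for (e in seq_len(nrow(edges))) {
          par <- st[edges[e, 1]]
          ch <- edges[e, 2]
          pr <- if (ch <= nt) {
            c0 <- codes[ch, s]
            if (c0 == 4L) 1 else Ps[[e]][par, c0 + 1]
          } else {
            Ps[[e]][par, st[ch]]
          }
          p <- p * pr
        }
        sumL <- sumL + p
      }
      gam <- gam + sumL / length(rates)
    }
    siteL <- model@pInv * inv + (1 - model@pInv) * gam
    total <- total + log(unname(siteL))
  }
  as.numeric(total)
}
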