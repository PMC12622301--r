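# Tree-MSA simulation: uniform random binary topologies, exponential branch
# lengths with a per-tree rate lambda drawn log-uniformly from [2, 5],
# GTR+I+G site evolution with parameters drawn from documented priors, and
# deletion-induced gaps. All randomness goes through R's RNG; dataset
# generation derives one substream seed per pair so output is a pure
# function of (manifest, seed).

#' Sample a uniform random binary topology
#'
#' Draws uniformly from the labeled unrooted binary topologies on
#' `nTaxa` leaves, realized by sequential insertion: starting from the
#' 3-leaf star, each further leaf is attached to a uniformly chosen
#' existing edge. Every unrooted labeled topology arises with equal
#' probability under this construction.
#'
#' @param nTaxa number of leaves, at least 3.
#' @param labels optional character vector of leaf labels (default
#'   `t1..tn`).
#' @return An unrooted `ape::phylo` topology (no branch lengths).
#' @export
sampleTopology <- function(nTaxa, labels = NULL) {
  if (nTaxa < 3L) stop("need at least 3 taxa")
  if (is.null(labels)) labels <- paste0("t", seq_len(nTaxa))
  stopifnot(length(labels) == nTaxa, !anyDuplicated(labels))
  # adjacency as an edge list over node ids; leaves are 1..nTaxa,
  # internal nodes get ids above nTaxa
  edges <- matrix(c(nTaxa + 1L, 1L, nTaxa + 1L, 2L, nTaxa + 1L, 3L),
                  ncol = 2L, byrow = TRUE)
  nextInternal <- nTaxa + 2L
  for (leaf in seq_len(nTaxa)[-(1:3)]) {
    e <- sample.int(nrow(edges), 1L)
    a <- edges[e, 1L]; b <- edges[e, 2L]
    v <- nextInternal; nextInternal <- nextInternal + 1L
    edges[e, ] <- c(a, v)
    edges <- rbind(edges, c(v, b), c(v, leaf))
  }
  # serialize to Newick from the original trifurcating node
  kids <- split(edges[, 2L], edges[, 1L])
  sub <- function(node) {
    if (node <= nTaxa) return(labels[node])
    paste0("(", paste(vapply(kids[[as.character(node)]], sub, ""), collapse = ","), ")")
  }
  parseNewick(paste0(sub(nTaxa + 1L), ";"))
}

#' Assign i.i.d. exponential branch lengths
#'
#' Every branch gets an independent Exp(`lambda`) length (mean
#' `1/lambda`), the branch-length model used for simulated training data.
#'
#' @param tree an `ape::phylo` object.
#' @param lambda exponential rate parameter, > 0.
#' @return The tree with `edge.length` set.
#' @export
sampleBranchLengths <- function(tree, lambda) {
  stopifnot(inherits(tree, "phylo"), lambda > 0)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = lambda)
  tree
}

#' Draw a per-tree branch-length rate lambda
#'
#' `u ~ Uniform(log 2, log 5)`, `lambda = exp(u)`, i.e. log-uniform on
#' `[2, 5]`.
#'
#' @return A single numeric value in `[2, 5]`.
#' @export
sampleLambda <- function() exp(stats::runif(1L, log(2), log(5)))

#' Construct a GTR+I+G model
#'
#' @param rates numeric of length 6, exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT (relative; conventionally GT = 1).
#' @param baseFreqs numeric of length 4 (A, C, G, T), positive, summing
#'   to 1.
#' @param gammaShape gamma shape alpha (> 0, `Inf` disables rate
#'   heterogeneity).
#' @param pInv proportion of invariant sites in `[0, 1)`.
#' @param nCategories number of discrete gamma categories.
#' @return A [GTRModel][GTRModel-class] object.
#' @export
gtrModel <- function(rates = rep(1, 6), baseFreqs = rep(0.25, 4),
                     gammaShape = 1, pInv = 0, nCategories = 4L) {
  rates <- stats::setNames(as.numeric(rates), c("AC", "AG", "AT", "CG", "CT", "GT"))
  baseFreqs <- stats::setNames(as.numeric(baseFreqs), c("A", "C", "G", "T"))
  new("GTRModel", rates = rates, baseFreqs = baseFreqs,
      gammaShape = as.numeric(gammaShape), pInv = as.numeric(pInv),
      nCategories = as.integer(nCategories))
}

#' Jukes-Cantor preset
#'
#' All exchangeabilities equal, uniform base frequencies, no invariant
#' sites, no rate heterogeneity.
#'
#' @return A [GTRModel][GTRModel-class] object.
#' @export
jcModel <- function() {
  gtrModel(rates = rep(1, 6), baseFreqs = rep(0.25, 4),
           gammaShape = Inf, pInv = 0, nCategories = 1L)
}

#' Sample GTR+I+G parameters from the default priors
#'
#' Base frequencies ~ Dirichlet(5,5,5,5); the five free exchangeabilities
#' log-uniform on `[0.1, 10]` with GT fixed at 1; gamma shape ~
#' Uniform(0.2, 5); invariant proportion ~ Uniform(0, 0.5); 4 discrete
#' gamma categories.
#'
#' @return A [GTRModel][GTRModel-class] object.
#' @export
sampleGTRModel <- function() {
  g <- stats::rgamma(4L, shape = 5)
  freqs <- g / sum(g)
  r <- exp(stats::runif(5L, log(0.1), log(10)))
  gtrModel(rates = c(r, 1), baseFreqs = freqs,
           gammaShape = stats::runif(1L, 0.2, 5),
           pInv = stats::runif(1L, 0, 0.5), nCategories = 4L)
}

# per-site rates: 0 for invariant sites, else a discrete gamma category
.siteRates <- function(model, L) {
  rates <- gammaCategoryRates(model)
  inv <- stats::runif(L) < model@pInv
  cat <- sample.int(length(rates), L, replace = TRUE)
  r <- rates[cat]
  r[inv] <- 0
  r
}

#' Evolve sequences along a tree under GTR+I+G
#'
#' The root sequence is drawn from the stationary base frequencies. Each
#' site is invariant with probability `pInv`, otherwise it gets a discrete
#' gamma rate category (mean-1 median discretization). Child states are
#' drawn from the transition matrix `P(rate * t)` along each branch. Only
#' leaf rows are returned, in tree tip order.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param model a [GTRModel][GTRModel-class].
#' @param L alignment length (>= 1).
#' @return A [PhyloMSA][PhyloMSA-class] with N = number of tips.
#' @export
evolveSequences <- function(tree, model, L) {
  stopifnot(inherits(tree, "phylo"), L >= 1L)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must have branch lengths")
  }
  rm <- gtrRateMatrix(model)
  nt <- length(tree$tip.label)
  rates <- .siteRates(model, L)
  groups <- split(seq_len(L), rates)
  rateOf <- as.numeric(names(groups))

  nNodes <- nt + tree$Nnode
  states <- matrix(NA_integer_, nNodes, L)
  root <- nt + 1L
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = rm$pi)
  ord <- ape::reorder.phylo(tree, "postorder")
  edgeOrder <- rev(seq_len(nrow(ord$edge)))  # preorder: parents before children
  for (k in edgeOrder) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    t <- ord$edge.length[k]
    for (gi in seq_along(groups)) {
      sites <- groups[[gi]]
      r <- rateOf[gi]
      if (r == 0 || t == 0) {
        states[ch, sites] <- states[p, sites]
      } else {
        P <- transitionProbs(rm, r * t)
        par <- states[p, sites]
        u <- stats::runif(length(sites))
        cum <- t(apply(P, 1L, cumsum))
        states[ch, sites] <- max.col(cum[par, , drop = FALSE] >= u, "first")
      }
    }
  }
  codes <- states[seq_len(nt), , drop = FALSE] - 1L
  rownames(codes) <- tree$tip.label
  new("PhyloMSA", codes = matrix(as.integer(codes), nrow = nt,
                                 dimnames = list(tree$tip.label, NULL)))
}

#' Introduce alignment gaps by per-lineage deletion events
#'
#' Each sequence independently receives a Poisson number of deletion
#' events with geometrically distributed lengths (mean 3 columns), placed
#' uniformly; affected positions become `-`. The event intensity is tuned
#' so the expected deleted fraction per sequence equals `deletionRate`.
#' The column count is unchanged. With the training grid of rates (0 to
#' 0.03) realized gap ratios stay far below 0.3.
#'
#' @param msa a [PhyloMSA][PhyloMSA-class].
#' @param deletionRate expected deleted fraction per sequence, in
#'   `[0, 1)`.
#' @param meanLength mean deletion tract length in columns.
#' @return A [PhyloMSA][PhyloMSA-class] with gaps introduced.
#' @export
applyDeletions <- function(msa, deletionRate, meanLength = 3) {
  stopifnot(deletionRate >= 0, deletionRate < 1)
  if (deletionRate == 0) return(msa)
  codes <- msa@codes
  L <- ncol(codes)
  for (i in seq_len(nrow(codes))) {
    nEvents <- stats::rpois(1L, deletionRate * L / meanLength)
    if (nEvents == 0L) next
    starts <- sample.int(L, nEvents, replace = TRUE)
    lens <- stats::rgeom(nEvents, prob = 1 / meanLength) + 1L
    for (e in seq_len(nEvents)) {
      codes[i, starts[e]:min(L, starts[e] + lens[e] - 1L)] <- 4L
    }
  }
  new("PhyloMSA", codes = codes)
}

#' Simulate a dataset of tree-MSA pairs
#'
#' For each manifest row, `count` independent pairs are generated: a
#' uniform topology on `nTaxa` leaves, exponential branch lengths with a
#' fresh log-uniform lambda in `[2, 5]`, substitution parameters (fresh
#' GTR+I+G draw, or the Jukes-Cantor preset), sequence evolution of
#' `seqLength` sites, and a deletion rate drawn uniformly from
#' `deletionGrid`. Each pair uses its own RNG substream derived from
#' `seed`, so the output is reproducible and per-pair order-independent.
#'
#' @param manifest data frame with columns `nTaxa`, `seqLength`, `count`.
#' @param seed integer seed.
#' @param model `"gtr"` (fresh parameter draw per pair) or `"jc"`.
#' @param deletionGrid deletion rates sampled uniformly per pair.
#' @param dir if non-NULL, write `pair<i>.nwk` / `pair<i>.fasta` files and
#'   a tab-separated `manifest.tsv` there instead of keeping pairs in
#'   memory.
#' @return A list with `pairs` (list of `list(tree, msa, meta)`; empty
#'   when `dir` is given) and `summary` (data frame: total pair count and
#'   per-row counts).
#' @export
simulateDataset <- function(manifest, seed, model = c("gtr", "jc"),
                            deletionGrid = c(0, 0.01, 0.02, 0.03),
                            dir = NULL) {
  model <- match.arg(model)
  stopifnot(all(c("nTaxa", "seqLength", "count") %in% names(manifest)))
  total <- sum(manifest$count)
  set.seed(seed)
  pairSeeds <- sample.int(.Machine$integer.max, max(total, 1L))
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  pairs <- if (is.null(dir)) vector("list", total) else list()
  meta <- vector("list", total)
  idx <- 0L
  for (r in seq_len(nrow(manifest))) {
    for (c in seq_len(manifest$count[r])) {
      idx <- idx + 1L
      set.seed(pairSeeds[idx])
      lambda <- sampleLambda()
      tree <- sampleBranchLengths(sampleTopology(manifest$nTaxa[r]), lambda)
      gm <- if (model == "jc") jcModel() else sampleGTRModel()
      delRate <- deletionGrid[sample.int(length(deletionGrid), 1L)]
      msa <- applyDeletions(evolveSequences(tree, gm, manifest$seqLength[r]), delRate)
      meta[[idx]] <- data.frame(
        pair = idx, nTaxa = manifest$nTaxa[r], seqLength = manifest$seqLength[r],
        lambda = lambda, deletionRate = delRate, seed = pairSeeds[idx]
      )
      if (is.null(dir)) {
        pairs[[idx]] <- list(tree = tree, msa = msa, meta = meta[[idx]])
      } else {
        cat(writeNewick(tree), "\n", sep = "",
            file = file.path(dir, sprintf("pair%05d.nwk", idx)))
        writeMSA(msa, file.path(dir, sprintf("pair%05d.fasta", idx)))
      }
    }
  }
  metaDf <- do.call(rbind, meta)
  if (!is.null(dir) && !is.null(metaDf)) {
    utils::write.table(metaDf, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(pairs = pairs,
       summary = data.frame(totalPairs = total, rows = nrow(manifest)),
       meta = metaDf)
}

#' Paper-scale manifest constructors
#'
#' `trainingManifest()` describes the full-scale training design: 50-taxon
#' pairs at 29 sequence lengths (128 to 1,024 nt in 32-nt steps), 1,000
#' pairs per length — 29,000 pairs in total. `testManifest()` describes
#' the matching test design: 128 pairs for each of five
#' (taxa, length) configurations — 20/50/100 taxa at 1,024 nt plus
#' 100 taxa at 256 and 512 nt — 640 pairs. These are descriptions only;
#' pass them (or a scaled-down slice) to [simulateDataset()] to generate
#' data.
#'
#' @return A data frame with columns `nTaxa`, `seqLength`, `count`.
#' @export
trainingManifest <- function() {
  data.frame(nTaxa = 50L, seqLength = seq(128L, 1024L, by = 32L), count = 1000L)
}

#' @rdname trainingManifest
#' @export
testManifest <- function() {
  data.frame(nTaxa = c(20L, 50L, 100L, 100L, 100L),
             seqLength = c(1024L, 1024L, 1024L, 256L, 512L),
             count = 128L)
}
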