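#' @import methods
NULL

.NUC <- c("A", "C", "G", "T", "-")
.GAP_CODE <- 4L

#' Multiple sequence alignment of DNA with gaps
#'
#' `PhyloMSA` holds N aligned DNA sequences of equal length L over the
#' five-symbol alphabet A, C, G, T and `-` (gap/missing). Sequences are
#' stored integer-coded (A=0, C=1, G=2, T=3, gap=4) — the form consumed by
#' the sequence encoder and the pruning likelihood — with taxon labels as
#' row names. IUPAC ambiguity codes, `N` and `?` are mapped to gap on
#' construction; input is case-insensitive.
#'
#' @slot codes integer matrix, N x L, values in 0..4, row names = labels.
#'
#' @seealso [phyloMSA()], [readMSA()], [msaSequences()], [gapRatio()]
#' @export
setClass("PhyloMSA", representation(codes = "matrix"))

setValidity("PhyloMSA", function(object) {
  m <- object@codes
  if (!is.matrix(m) || !is.integer(m)) return("codes must be an integer matrix")
  if (nrow(m) < 2L) return("an alignment needs at least 2 sequences")
  if (ncol(m) < 1L) return("an alignment needs at least 1 column")
  if (anyNA(m) || any(m < 0L) || any(m > 4L)) return("codes must be in 0..4")
  lab <- rownames(m)
  if (is.null(lab) || any(!nzchar(lab))) return("all taxa must be labeled")
  if (anyDuplicated(lab)) {
    return(paste("duplicate labels:", paste(unique(lab[duplicated(lab)]), collapse = ", ")))
  }
  TRUE
})

#' GTR+I+G substitution model parameters
#'
#' General time-reversible model with a proportion of invariant sites (+I)
#' and discrete-gamma rate heterogeneity across sites (+G). Exchangeabilities
#' are relative (r_GT conventionally 1); the rate matrix built from these
#' parameters is normalized to one expected substitution per site per unit
#' branch length at stationarity. `gammaShape = Inf` disables rate
#' heterogeneity (all categories rate 1), which together with
#' `nCategories = 1` gives rate-homogeneous models such as Jukes-Cantor.
#'
#' @slot rates named numeric of length 6 (AC, AG, AT, CG, CT, GT), all > 0.
#' @slot baseFreqs named numeric of length 4 (A, C, G, T), positive, sum 1.
#' @slot gammaShape positive numeric (alpha), possibly `Inf`.
#' @slot pInv numeric in `[0, 1)`, proportion of invariant sites.
#' @slot nCategories positive integer count of discrete gamma categories.
#'
#' @seealso [gtrModel()], [jcModel()], [sampleGTRModel()], [gtrRateMatrix()]
#' @export
setClass("GTRModel", representation(
  rates = "numeric", baseFreqs = "numeric", gammaShape = "numeric",
  pInv = "numeric", nCategories = "integer"
))

setValidity("GTRModel", function(object) {
  if (length(object@rates) != 6L || any(object@rates <= 0)) {
    return("rates must be 6 positive exchangeabilities")
  }
  if (length(object@baseFreqs) != 4L || any(object@baseFreqs <= 0)) {
    return("baseFreqs must be 4 positive frequencies")
  }
  if (abs(sum(object@baseFreqs) - 1) > 1e-8) return("baseFreqs must sum to 1")
  if (length(object@gammaShape) != 1L || object@gammaShape <= 0) {
    return("gammaShape must be a single positive value (possibly Inf)")
  }
  if (length(object@pInv) != 1L || object@pInv < 0 || object@pInv > 1) {
    return("pInv must lie in [0, 1]")
  }
  if (length(object@nCategories) != 1L || object@nCategories < 1L) {
    return("nCategories must be a positive integer")
  }
  TRUE
})

#' Learnable neighbor-joining model
#'
#' Holds the configuration and the weights of the full encoder-decoder
#' stack: the axial-attention MSA encoder, the gated parent-node estimator,
#' the ancestral-context cross-attention and the subtree evaluator MLP.
#' Create with [neuralNJModel()]; train with [trainSupervised()] or
#' [reinforceFinetune()]; run with [greedyBuild()], [sampleBuild()] or
#' [mcSearch()].
#'
#' @slot config named list: dModel, nLayers, nHeads, hiddenMult, maxLen.
#' @slot params named list of numeric weight matrices.
#'
#' @export
setClass("NeuralNJModel", representation(config = "list", params = "list"))

setValidity("NeuralNJModel", function(object) {
  cfg <- object@config
  need <- c("dModel", "nLayers", "nHeads", "hiddenMult", "maxLen")
  if (!all(need %in% names(cfg))) {
    return(paste("config must contain:", paste(need, collapse = ", ")))
  }
  if (cfg$dModel %% cfg$nHeads != 0) return("dModel must be divisible by nHeads")
  if (!all(vapply(object@params, is.matrix, TRUE))) {
    return("all params must be matrices")
  }
  if (any(!vapply(object@params, function(p) all(is.finite(p)), TRUE))) {
    return("all weights must be finite")
  }
  TRUE
})

# ---- generics -----------------------------------------------------------

#' @rdname PhyloMSA-accessors
#' @export
setGeneric("msaLabels", function(x) standardGeneric("msaLabels"))

#' @rdname PhyloMSA-accessors
#' @export
setGeneric("msaCodes", function(x) standardGeneric("msaCodes"))

#' @rdname PhyloMSA-accessors
#' @export
setGeneric("msaSequences", function(x) standardGeneric("msaSequences"))

#' @rdname PhyloMSA-accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @rdname PhyloMSA-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname gapRatio
#' @export
setGeneric("gapRatio", function(x) standardGeneric("gapRatio"))

#' Accessors for PhyloMSA objects
#'
#' `msaLabels` returns the taxon labels, `msaCodes` the integer-coded
#' N x L matrix (A=0, C=1, G=2, T=3, gap=4), `msaSequences` the decoded
#' character sequences (named character vector), `nTaxa` and `nSites` the
#' alignment dimensions. Coding and decoding are mutually inverse.
#'
#' @param x a [PhyloMSA][PhyloMSA-class] object.
#' @return See individual descriptions.
#' @name PhyloMSA-accessors
NULL

#' @rdname PhyloMSA-accessors
setMethod("msaLabels", "PhyloMSA", function(x) rownames(x@codes))

#' @rdname PhyloMSA-accessors
setMethod("msaCodes", "PhyloMSA", function(x) x@codes)

#' @rdname PhyloMSA-accessors
setMethod("msaSequences", "PhyloMSA", function(x) {
  seqs <- apply(x@codes, 1L, function(row) paste(.NUC[row + 1L], collapse = ""))
  names(seqs) <- rownames(x@codes)
  seqs
})

#' @rdname PhyloMSA-accessors
setMethod("nTaxa", "PhyloMSA", function(x) nrow(x@codes))

#' @rdname PhyloMSA-accessors
setMethod("nSites", "PhyloMSA", function(x) ncol(x@codes))

#' Fraction of gap symbols in an alignment
#'
#' The number of gap cells divided by N*L.
#'
#' @param x a [PhyloMSA][PhyloMSA-class] object.
#' @return A value in `[0, 1]`.
#' @export
#' @rdname gapRatio
setMethod("gapRatio", "PhyloMSA", function(x) mean(x@codes == .GAP_CODE))

setMethod("show", "PhyloMSA", function(object) {
  cat(sprintf("PhyloMSA: %d taxa, %d sites, gap ratio %.3f\n",
              nrow(object@codes), ncol(object@codes), gapRatio(object)))
  lab <- rownames(object@codes)
  k <- min(5L, length(lab))
  for (i in seq_len(k)) {
    s <- paste(.NUC[object@codes[i, seq_len(min(40L, ncol(object@codes)))] + 1L],
               collapse = "")
    cat(sprintf("  %-12s %s%s\n", lab[i], s, if (ncol(object@codes) > 40L) "..." else ""))
  }
  if (length(lab) > k) cat(sprintf("  ... and %d more\n", length(lab) - k))
})

setMethod("show", "GTRModel", function(object) {
  cat("GTRModel (GTR+I+G)\n")
  cat("  exchangeabilities:",
      paste(sprintf("%s=%.3f", names(object@rates), object@rates), collapse = " "), "\n")
  cat("  base frequencies: ",
      paste(sprintf("%s=%.3f", names(object@baseFreqs), object@baseFreqs), collapse = " "), "\n")
  cat(sprintf("  gamma shape %s, pInv %.3f, %d rate categories\n",
              format(object@gammaShape), object@pInv, object@nCategories))
})

setMethod("show", "NeuralNJModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("NeuralNJModel: d=%d, %d layer(s), %d head(s), %s parameters\n",
              cfg$dModel, cfg$nLayers, cfg$nHeads, format(np, big.mark = ",")))
})
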