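# Tree utilities: Newick I/O, bipartitions, Robinson-Foulds distance,
# patristic distances, and the classical Saitou-Nei NJ baseline.
# Trees are ape "phylo" objects throughout; unrooted trees carry the usual
# trifurcating root. Labels are restricted to [A-Za-z0-9_.-] (unquoted
# Newick dialect, "." decimals, ";" terminator).

.checkLabels <- function(labels) {
  bad <- labels[!grepl("^[A-Za-z0-9_.-]+$", labels)]
  if (length(bad)) {
    stop("labels outside the [A-Za-z0-9_.-] Newick dialect: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(labels)
}

#' Parse a Newick string into a phylo tree
#'
#' Accepts standard unquoted Newick with optional branch lengths. Stricter
#' than `ape::read.tree`: unbalanced parentheses, empty input and duplicate
#' leaf labels are errors.
#'
#' @param text a single Newick string, e.g. `"((A:1,B:1):0.5,C:2);"`.
#' @return An `ape::phylo` tree.
#' @examples
#' tr <- parseNewick("((A,B),(C,D));")
#' @seealso [writeNewick()]
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n.open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n.close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n.open != n.close) {
    stop(sprintf("unbalanced parentheses in Newick: %d '(' vs %d ')'", n.open, n.close))
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree)) stop("failed to parse Newick string: ", substr(text, 1L, 60L))
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty leaf label in Newick string")
  tree
}

#' Write a phylo tree as a Newick string
#'
#' Branch lengths are emitted when present; unrooted trees keep their
#' trifurcating root. The output reparses (via [parseNewick()]) to a tree
#' with the identical bipartition set.
#'
#' @param tree an `ape::phylo` object.
#' @return A single Newick string terminated by `";"`.
#' @export
writeNewick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  .checkLabels(tree$tip.label)
  ape::write.tree(tree)
}

.splitKey <- function(members) paste(sort(members), collapse = "\r")

# Leaf-label sets below every edge of the tree (tree rooted as stored).
.edgeClades <- function(tree) {
  nt <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k) below[[tree$edge[k, 2L]]])
}

#' Nontrivial bipartitions (splits) of an unrooted tree
#'
#' Removing an internal edge partitions the leaves into two sets; only
#' nontrivial splits (both sides with at least 2 leaves) are returned, each
#' as its lexicographically smaller side. A binary unrooted tree on N
#' leaves has exactly N-3 such splits; trees with fewer than 4 leaves have
#' none.
#'
#' @param tree an `ape::phylo` object.
#' @return A list of character vectors (sorted leaf labels), with the full
#'   label set in `attr(, "taxa")`.
#' @export
treeBipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- sort(tree$tip.label)
  nt <- length(taxa)
  out <- list()
  if (nt >= 4L) {
    seen <- character(0)
    for (side in .edgeClades(tree)) {
      if (length(side) < 2L || length(side) > nt - 2L) next
      other <- setdiff(taxa, side)
      a <- sort(side); b <- sort(other)
      canonical <- if (paste(a, collapse = "\r") <= paste(b, collapse = "\r")) a else b
      key <- .splitKey(canonical)
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- canonical
      }
    }
  }
  attr(out, "taxa") <- taxa
  out
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the splits unique to each tree. The normalized form divides by
#' 2(N-3), the maximum attainable for two binary unrooted trees on N
#' leaves, giving a value in `[0, 1]`: 0 for identical topologies, 1 when
#' no nontrivial split is shared. Rootings are ignored (splits only).
#'
#' @param t1,t2 `ape::phylo` trees on the same leaf-label set.
#' @return A list with components `raw` (integer) and `normalized`.
#' @examples
#' rfDistance(parseNewick("((A,B),(C,D));"), parseNewick("((A,C),(B,D));"))
#' @export
rfDistance <- function(t1, t2) {
  s1 <- treeBipartitions(t1)
  s2 <- treeBipartitions(t2)
  if (!identical(attr(s1, "taxa"), attr(s2, "taxa"))) {
    only1 <- setdiff(attr(s1, "taxa"), attr(s2, "taxa"))
    only2 <- setdiff(attr(s2, "taxa"), attr(s1, "taxa"))
    stop("leaf sets differ; only in first: {",
         paste(only1, collapse = ","), "}; only in second: {",
         paste(only2, collapse = ","), "}")
  }
  k1 <- vapply(s1, .splitKey, "")
  k2 <- vapply(s2, .splitKey, "")
  raw <- sum(!(k1 %in% k2)) + sum(!(k2 %in% k1))
  n <- length(attr(s1, "taxa"))
  denom <- 2L * max(n - 3L, 0L)
  list(raw = as.integer(raw), normalized = if (denom > 0L) raw / denom else 0)
}

#' Patristic (path-length) distances between all leaf pairs
#'
#' `d[i, j]` is the sum of branch lengths on the tree path between leaves
#' i and j; by construction the matrix is additive with respect to the
#' tree and satisfies the four-point condition on every quartet.
#'
#' @param tree an `ape::phylo` object with all branch lengths present.
#' @return A symmetric numeric matrix with the tip labels as dimnames.
#' @export
patristicDistances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1L]
    stop(sprintf("missing branch length on edge %d (%d -> %d)",
                 bad, tree$edge[bad, 1L], tree$edge[bad, 2L]))
  }
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Classical neighbor joining (Saitou-Nei)
#'
#' Iteratively joins the pair (i, j) minimizing
#' `Q(i, j) = (k - 2) d(i, j) - sum_m d(i, m) - sum_m d(j, m)`,
#' estimates the two branch lengths, and collapses the pair with the
#' standard distance update, until three nodes remain; those are connected
#' to a final trifurcating root. Ties are broken by the smallest (i, j)
#' index pair, and negative branch-length estimates are clamped to zero
#' (topology unaffected). On an additive distance matrix from a binary
#' tree with positive internal branches the true topology is recovered
#' exactly.
#'
#' @param dm square symmetric numeric matrix with zero diagonal and taxon
#'   labels as dimnames (at least 3 taxa).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighborJoining <- function(dm) {
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- colnames(dm)
  if (is.null(labels)) stop("distance matrix must have labels as dimnames")
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) stop("distance matrix must be symmetric")
  if (any(!is.finite(dm)) || any(dm < 0)) stop("distances must be finite and nonnegative")
  .checkLabels(labels)

  d <- dm
  nwk <- labels  # growing Newick fragments per active node
  repeat {
    k <- nrow(d)
    if (k == 3L) break
    R <- rowSums(d)
    Q <- (k - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    # smallest Q; ties -> smallest (i, j) with i < j
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in 1L:(k - 1L)) {
      for (j in (i + 1L):k) {
        if (Q[i, j] < bestQ - 1e-12) {
          bestQ <- Q[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    vi <- 0.5 * d[i, j] + (R[i] - R[j]) / (2 * (k - 2))
    vj <- d[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    newRow <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], vi, nwk[j], vj)
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newRow[keep]),
               c(newRow[keep], 0))
    nwk <- c(nwk[keep], merged)
  }
  v1 <- max(0.5 * (d[1, 2] + d[1, 3] - d[2, 3]), 0)
  v2 <- max(0.5 * (d[1, 2] + d[2, 3] - d[1, 3]), 0)
  v3 <- max(0.5 * (d[1, 3] + d[2, 3] - d[1, 2]), 0)
  text <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nwk[1], v1, nwk[2], v2, nwk[3], v3)
  parseNewick(text)
}

#' Read and write distance matrices as tab-separated text
#'
#' The format is a square numeric table with a header row of labels and
#' the label repeated in the first column; it round-trips through
#' [neighborJoining()] inputs.
#'
#' @param path file path.
#' @return `readDistanceMatrix` returns a labeled symmetric matrix.
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("distance matrix file must be square with matching labels")
  }
  m
}

#' @param dm labeled square matrix (e.g. from [patristicDistances()]).
#' @rdname readDistanceMatrix
#' @export
writeDistanceMatrix <- function(dm, path) {
  utils::write.table(as.data.frame(dm), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
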