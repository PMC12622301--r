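# Alignment constructors and FASTA / relaxed-PHYLIP readers and writers.
# The canonical in-memory form is the integer-coded PhyloMSA (A=0, C=1,
# G=2, T=3, gap=4). Ambiguity codes (R,Y,S,W,K,M,B,D,H,V,N), '?' and '.'
# are treated as missing and coded as gap; 'U' is read as 'T'.

.CODE_MAP <- local({
  m <- rep(NA_integer_, 256L)
  set <- function(chars, code) {
    for (ch in chars) m[utf8ToInt(ch) + 1L] <<- code
  }
  set(c("A", "a"), 0L); set(c("C", "c"), 1L); set(c("G", "g"), 2L)
  set(c("T", "t", "U", "u"), 3L)
  amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "-", "?", ".")
  set(c(amb, tolower(amb)), 4L)
  m
})

.encodeSeq <- function(s) {
  codes <- .CODE_MAP[utf8ToInt(s) + 1L]
  if (anyNA(codes)) {
    bad <- substr(s, which(is.na(codes))[1L], which(is.na(codes))[1L])
    stop("unrecognized symbol '", bad, "' in sequence")
  }
  codes
}

#' Construct a PhyloMSA from character sequences
#'
#' @param sequences a named character vector of equal-length aligned DNA
#'   sequences (names are the taxon labels), or an unnamed vector together
#'   with `labels`.
#' @param labels optional character vector of taxon labels.
#' @return A [PhyloMSA][PhyloMSA-class] object.
#' @examples
#' phyloMSA(c(A = "ACGT", B = "AC-T"))
#' @export
phyloMSA <- function(sequences, labels = names(sequences)) {
  stopifnot(is.character(sequences), length(sequences) >= 2L)
  if (is.null(labels)) stop("taxon labels are required")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment; per-sequence lengths: ",
         paste(sprintf("%s=%d", labels, lens), collapse = ", "))
  }
  codes <- t(vapply(sequences, .encodeSeq, integer(lens[1L])))
  if (lens[1L] == 1L) codes <- matrix(as.integer(codes), ncol = 1L)
  rownames(codes) <- labels
  new("PhyloMSA", codes = codes)
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' FASTA: `>label` header lines, sequence possibly wrapped. Relaxed
#' PHYLIP: a header line `N L`, then one whitespace-delimited
#' `label sequence` record per taxon (sequential; interleaved continuation
#' blocks are also accepted). Symbols are uppercased; ambiguity codes and
#' `N` become gaps.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`; the default guesses from the
#'   first non-blank character (`>` means FASTA).
#' @return A [PhyloMSA][PhyloMSA-class] object.
#' @seealso [writeMSA()]
#' @export
readMSA <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty alignment file: ", path)
  if (format == "auto") {
    format <- if (startsWith(trimws(lines[1L]), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") .readFasta(lines) else .readPhylip(lines)
}

.readFasta <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found")
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- vapply(strsplit(labels, "\\s+"), `[`, "", 1L)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(gsub("\\s", "", lines[(hdr[i] + 1L):ends[i]]), collapse = "")
  }, "")
  phyloMSA(seqs, labels)
}

.readPhylip <- function(lines) {
  head <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(head) < 2L) stop("malformed PHYLIP header: ", lines[1L])
  n <- as.integer(head[1L]); L <- as.integer(head[2L])
  if (is.na(n) || is.na(L)) stop("malformed PHYLIP header: ", lines[1L])
  body <- lines[-1L]
  if (length(body) < n) stop("PHYLIP file has fewer records than the header declares")
  labels <- character(n); seqs <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    labels[i] <- tok[1L]
    seqs[i] <- paste(tok[-1L], collapse = "")
  }
  extra <- body[-seq_len(n)]
  i <- 0L
  for (line in extra) {  # interleaved continuation blocks cycle over taxa
    i <- i %% n + 1L
    seqs[i] <- paste0(seqs[i], gsub("\\s", "", line))
  }
  if (any(nchar(seqs) != L)) {
    stop("PHYLIP sequence lengths disagree with header: ",
         paste(sprintf("%s=%d", labels, nchar(seqs)), collapse = ", "),
         " (expected ", L, ")")
  }
  phyloMSA(seqs, labels)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @param msa a [PhyloMSA][PhyloMSA-class] object.
#' @param path output file path.
#' @param format `"fasta"` (default, wrapped at 60 columns) or `"phylip"`
#'   (relaxed sequential, full labels).
#' @return `path`, invisibly.
#' @export
writeMSA <- function(msa, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- msaSequences(msa)
  if (format == "fasta") {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(paste0(">", names(seqs)[i]), con)
      s <- seqs[[i]]
      starts <- seq(1L, nchar(s), by = 60L)
      writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
    }
  } else {
    lines <- c(sprintf("%d %d", nTaxa(msa), nSites(msa)),
               sprintf("%s  %s", names(seqs), unname(seqs)))
    writeLines(lines, path)
  }
  invisible(path)
}
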