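#' @describeIn SimilarityGraph protein node identifiers.
#' @param x,object a SimilarityGraph.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @export
setMethod("nodes", "SimilarityGraph", function(x) x@nodes)

#' @describeIn SimilarityGraph edge table (`from`, `to`, `weight`).
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @export
setMethod("edges", "SimilarityGraph", function(x) x@edges)

#' @export
setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf("SimilarityGraph: %d proteins, %d edges (cutoff %g)\n",
              length(object@nodes), nrow(object@edges), object@cutoff))
  invisible(object)
})

newSimilarityGraph <- function(nodes, from, to, weight, cutoff,
                               genomeMap = character()) {
  # canonical undirected orientation, max-aggregate duplicates
  a <- pmin(from, to); b <- pmax(from, to)
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    w <- tapply(weight, key, max)
    ab <- strsplit(names(w), "\r", fixed = TRUE)
    a <- vapply(ab, `[`, character(1), 1L)
    b <- vapply(ab, `[`, character(1), 2L)
    weight <- as.numeric(w)
  }
  o <- order(a, b)
  new("SimilarityGraph", nodes = sort(unique(nodes)),
      edges = data.frame(from = a[o], to = b[o], weight = weight[o],
                         stringsAsFactors = FALSE),
      cutoff = cutoff, genomeMap = genomeMap)
}

#' Read an all-vs-all similarity table into a SimilarityGraph
#'
#' Parses the standard 12-column tab-separated all-vs-all dialect (qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore). Hits with an e-value above `cutoff` are discarded
#' (default 1e-5, the customary ortholog-detection significance threshold),
#' self-hits are dropped, and reciprocal hits are merged into a single
#' undirected edge keeping the larger transformed score.
#'
#' @param path path to the tab-separated hit table (no header).
#' @param scoreColumn edge-weight source: `"neg_log_evalue"` (default;
#'   \eqn{-\log_{10}} e-value capped at 200, the usual monotone bounded
#'   transform) or `"bitscore"`.
#' @param cutoff e-value significance cutoff (hits above it are dropped).
#' @param genomeMap optional named character vector protein id -> genome id,
#'   carried on the graph for downstream genome projection.
#' @return a [SimilarityGraph-class].
#' @export
readSimilarityTable <- function(path, scoreColumn = c("neg_log_evalue", "bitscore"),
                                cutoff = 1e-5, genomeMap = character()) {
  scoreColumn <- match.arg(scoreColumn)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0) stop("empty similarity table: ", path)
  bad <- which(nf != 12)
  if (length(bad))
    stop(sprintf("malformed similarity table %s: line %d has %d fields (12 expected)",
                 path, bad[1], nf[bad[1]]))
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                   col.names = cols,
                   colClasses = c("character", "character", rep("numeric", 10)))
  if (any(is.na(df$evalue)) || any(is.na(df$bitscore)))
    stop("non-numeric evalue/bitscore fields in ", path)
  nodesAll <- unique(c(df$qseqid, df$sseqid))
  keep <- df$evalue <= cutoff & df$qseqid != df$sseqid
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) {
    cond <- simpleError(sprintf("no edges remain in %s after the %g cutoff", path, cutoff))
    class(cond) <- c("noEdgesError", class(cond))
    stop(cond)
  }
  weight <- if (scoreColumn == "neg_log_evalue") {
    pmin(-log10(pmax(df$evalue, 1e-200)), 200)
  } else df$bitscore
  newSimilarityGraph(nodesAll, df$qseqid, df$sseqid, weight, cutoff, genomeMap)
}

aaAlphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# shared-k-mer candidate screen: pairs of sequences with >= 1 common k-mer
kmerCandidates <- function(seqs, k) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    L <- nchar(s)
    if (L < k) next
    kmers <- unique(substring(s, 1:(L - k + 1), k:L))
    for (km in kmers) assign(km, c(get0(km, idx, ifnotfound = integer()), i), idx)
  }
  pairs <- new.env(parent = emptyenv())
  for (km in ls(idx)) {
    hits <- get(km, idx)
    if (length(hits) > 1) {
      for (u in seq_along(hits)) for (v in seq_len(u - 1L)) {
        key <- paste(hits[v], hits[u])
        assign(key, TRUE, pairs)
      }
    }
  }
  keys <- ls(pairs)
  if (!length(keys)) return(matrix(integer(), ncol = 2))
  do.call(rbind, lapply(strsplit(keys, " "), as.integer))
}

#' Score all-vs-all protein similarities with a built-in aligner
#'
#' Self-contained replacement for an external all-vs-all sequence search:
#' candidate pairs are screened by sharing at least one length-`k` k-mer,
#' then scored by global (Needleman-Wunsch) alignment under BLOSUM62 with
#' affine gap costs. Pairs whose alignment score does not exceed
#' `minScore` are excluded. No e-value statistics are computed; edge
#' weights are raw alignment scores.
#'
#' @param proteins a named [Biostrings::AAStringSet] (unique ids).
#' @param k k-mer length for the candidate screen (default 5).
#' @param gapOpening,gapExtension affine gap costs (defaults 11 / 1).
#' @param minScore keep a pair only if its alignment score is strictly
#'   greater than this (default 0; graph weights must be positive).
#' @param genomeMap optional named protein id -> genome id map; when missing
#'   it is derived from ids of the form `<genome>|<rest>` where possible.
#' @return a [SimilarityGraph-class] with alignment-score weights.
#' @export
computeSimilarities <- function(proteins, k = 5L, gapOpening = 11,
                                gapExtension = 1, minScore = 0,
                                genomeMap = NULL) {
  stopifnot(is(proteins, "AAStringSet"))
  if (length(proteins) < 2) stop("need at least 2 protein records")
  ids <- names(proteins)
  if (is.null(ids) || anyDuplicated(ids)) stop("proteins must have unique names")
  seqs <- as.character(proteins)
  legal <- aaAlphabet()
  badSeq <- vapply(seqs, function(s)
    !all(strsplit(s, "")[[1]] %in% legal), logical(1))
  if (any(badSeq))
    stop("illegal amino-acid characters in: ", ids[which(badSeq)[1]])
  if (any(nchar(seqs) == 0)) stop("empty sequences are not allowed")
  if (is.null(genomeMap)) {
    genomeMap <- if (all(grepl("|", ids, fixed = TRUE)))
      setNames(sub("\\|.*$", "", ids), ids) else character()
  }
  cand <- kmerCandidates(seqs, k)
  if (nrow(cand) == 0)
    return(newSimilarityGraph(ids, character(), character(), numeric(),
                              cutoff = minScore, genomeMap = genomeMap))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  scores <- vapply(seq_len(nrow(cand)), function(r) {
    Biostrings::pairwiseAlignment(
      proteins[[cand[r, 1]]], proteins[[cand[r, 2]]],
      substitutionMatrix = get("BLOSUM62"), gapOpening = gapOpening,
      gapExtension = gapExtension, type = "global", scoreOnly = TRUE)
  }, numeric(1))
  keep <- scores > minScore
  newSimilarityGraph(ids, ids[cand[keep, 1]], ids[cand[keep, 2]],
                     scores[keep], cutoff = minScore, genomeMap = genomeMap)
}
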