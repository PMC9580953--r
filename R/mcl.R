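#' @describeIn OrthologClusterSet list of clusters (protein-id character
#'   vectors).
#' @param x,object an OrthologClusterSet.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @export
setMethod("clusters", "OrthologClusterSet", function(x) x@clusters)

#' @describeIn OrthologClusterSet named protein id -> genome id map.
#' @export
setGeneric("genomeMap", function(x) standardGeneric("genomeMap"))

#' @export
setMethod("genomeMap", "OrthologClusterSet", function(x) x@genomeMap)

#' @export
setMethod("length", "OrthologClusterSet", function(x) length(x@clusters))

#' @export
setMethod("show", "OrthologClusterSet", function(object) {
  sizes <- lengths(object@clusters)
  cat(sprintf("OrthologClusterSet: %d clusters over %d proteins (%d singletons)\n",
              length(sizes), sum(sizes), sum(sizes == 1)))
  if (!object@converged) cat("  warning: clustering did not converge\n")
  invisible(object)
})

#' Markov clustering of a protein similarity graph
#'
#' Partitions a weighted similarity graph into gene families by the Markov
#' Cluster (MCL) procedure: the column-stochastic transition matrix is
#' alternately expanded (matrix power, spreading flow along paths) and
#' inflated (entrywise power followed by column renormalization,
#' strengthening intra-cluster flow), with small entries pruned, until the
#' matrix change drops below `convergenceTol`. Clusters are read off the
#' attractor structure of the limit matrix; every node lands in exactly one
#' cluster and isolated nodes become singletons.
#'
#' Self-loops are added before iterating (weight = the node's maximum
#' incident edge weight, or 1 for isolated nodes), the standard
#' regularization that damps period-2 oscillation. A node attracted by
#' several attractor systems is assigned to the one with the largest
#' attraction value; exact ties go to the lexicographically smallest
#' cluster id, so the partition is deterministic and independent of input
#' order.
#'
#' @param graph a [SimilarityGraph-class].
#' @param expansion integer matrix-power exponent (>= 2, default 2).
#' @param inflation entrywise inflation exponent (> 1, default 2; larger
#'   values give finer clusters).
#' @param pruneThreshold entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param maxIterations iteration cap (default 100).
#' @param convergenceTol stop when the largest entrywise change of the
#'   matrix is below this (default 1e-6).
#' @param addSelfLoops add regularizing self-loops (default TRUE).
#' @return an [OrthologClusterSet-class]; if the iteration cap was reached
#'   first, the best partition so far with `converged = FALSE` and a
#'   warning. An attribute `"diagnostics"` records the iteration count and
#'   the largest deviation of any column sum from 1 observed after an
#'   inflation step.
#' @examples
#' g <- newSimilarityGraphFromEdges(
#'   data.frame(from = c("a", "a", "b", "d", "d", "e"),
#'              to   = c("b", "c", "c", "e", "f", "f"), weight = 1))
#' mclCluster(g)
#' @export
mclCluster <- function(graph, expansion = 2L, inflation = 2,
                       pruneThreshold = 1e-5, maxIterations = 100L,
                       convergenceTol = 1e-6, addSelfLoops = TRUE) {
  stopifnot(is(graph, "SimilarityGraph"))
  expansion <- assertCount(expansion, "expansion", min = 2L)
  if (inflation <= 1) stop("inflation must be > 1")
  if (pruneThreshold < 0) stop("pruneThreshold must be >= 0")
  maxIterations <- assertCount(maxIterations, "maxIterations", min = 1L)
  if (convergenceTol < 0) stop("convergenceTol must be >= 0")
  ids <- nodes(graph)
  n <- length(ids)
  if (n == 0) stop("graph has no nodes")

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- edges(graph)
  if (nrow(e)) {
    A[cbind(e$from, e$to)] <- e$weight
    A[cbind(e$to, e$from)] <- e$weight
  }
  if (addSelfLoops) {
    loop <- apply(A, 1L, max)
    loop[loop == 0] <- 1
    diag(A) <- loop
  } else {
    deg <- colSums(A)
    diag(A)[deg == 0] <- 1  # keep isolated columns stochastic
  }
  M <- sweep(A, 2L, colSums(A), "/")

  converged <- FALSE
  maxColSumDev <- 0
  it <- 0L
  for (it in seq_len(maxIterations)) {
    Mexp <- M
    for (p in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < pruneThreshold] <- 0
    cs <- colSums(Minf)
    dead <- cs == 0
    if (any(dead)) {           # column fully pruned: pin it to itself
      Minf[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Minf <- sweep(Minf, 2L, cs, "/")
    maxColSumDev <- max(maxColSumDev, abs(colSums(Minf) - 1))
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < convergenceTol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", maxIterations,
            " iterations; returning current partition")

  clusterList <- mclInterpret(M, pruneThreshold)
  out <- new("OrthologClusterSet", clusters = clusterList,
             genomeMap = graph@genomeMap, converged = converged)
  attr(out, "diagnostics") <- list(iterations = it,
                                   maxColSumDeviation = maxColSumDev)
  out
}

# Read clusters from the (near-)idempotent limit matrix: attractors are
# nodes retaining outgoing mass (nonzero rows); attractors reaching each
# other share a cluster; ordinary nodes attach to the attractor system with
# the largest attraction value (ties: lexicographically smallest cluster id).
mclInterpret <- function(M, eps) {
  ids <- rownames(M)
  n <- length(ids)
  attractors <- which(rowSums(M) > eps)
  if (!length(attractors)) attractors <- seq_len(n)

  # union attractors that attract one another
  comp <- seq_along(attractors)
  names(comp) <- attractors
  findRoot <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (ai in seq_along(attractors)) for (bi in seq_len(ai - 1L)) {
    a <- attractors[ai]; b <- attractors[bi]
    if (M[a, b] > eps || M[b, a] > eps) {
      ra <- findRoot(ai); rb <- findRoot(bi)
      if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(attractors), findRoot, integer(1))
  groups <- split(attractors, roots)

  clusterOf <- integer(n)                # 0 = unassigned
  for (gi in seq_along(groups)) clusterOf[groups[[gi]]] <- gi
  clusterId <- vapply(groups, function(g) min(ids[g]), character(1))

  for (v in which(clusterOf == 0L)) {
    pull <- vapply(groups, function(g) max(M[g, v]), numeric(1))
    best <- max(pull)
    if (best <= eps) {                   # unreachable: own singleton
      groups[[length(groups) + 1L]] <- v
      clusterId <- c(clusterId, ids[v])
      clusterOf[v] <- length(groups)
    } else {
      cand <- which(pull >= best - .Machine$double.eps * 4)
      clusterOf[v] <- cand[order(clusterId[cand])][1]
    }
  }
  out <- lapply(seq_along(groups), function(gi) sort(ids[clusterOf == gi]))
  names(out) <- vapply(out, `[`, character(1), 1L)
  out[lengths(out) > 0][order(names(out)[lengths(out) > 0])]
}

#' Build a SimilarityGraph directly from an edge table
#'
#' Convenience constructor for tests and small examples: undirected edges
#' with positive weights; nodes are inferred from the edge endpoints unless
#' given.
#'
#' @param edgeTable data.frame with columns `from`, `to`, `weight`.
#' @param nodes optional character vector of node ids (to include isolated
#'   nodes).
#' @param genomeMap optional named protein id -> genome id map.
#' @return a [SimilarityGraph-class].
#' @export
newSimilarityGraphFromEdges <- function(edgeTable, nodes = NULL,
                                        genomeMap = character()) {
  stopifnot(all(c("from", "to", "weight") %in% names(edgeTable)))
  allNodes <- unique(c(edgeTable$from, edgeTable$to, nodes))
  newSimilarityGraph(allNodes, as.character(edgeTable$from),
                     as.character(edgeTable$to), edgeTable$weight,
                     cutoff = NA_real_, genomeMap = genomeMap)
}

#' Project ortholog clusters onto a presence/absence matrix
#'
#' One row per cluster (gene family); a cell is `TRUE` when the cluster has
#' at least one member protein from that genome, so paralogs collapse to a
#' single presence. Column order follows `genomeOrder`.
#'
#' @param clusterSet an [OrthologClusterSet-class] with a complete genome
#'   map.
#' @param genomeOrder character vector of genome ids defining column order;
#'   every genome appearing in the map must be listed.
#' @return a [PresenceAbsence-class].
#' @export
clustersToMatrix <- function(clusterSet, genomeOrder) {
  stopifnot(is(clusterSet, "OrthologClusterSet"))
  gm <- genomeMap(clusterSet)
  if (!length(gm)) stop("clusterSet has no genome map")
  used <- unique(unname(gm[unlist(clusters(clusterSet), use.names = FALSE)]))
  missing <- setdiff(used, genomeOrder)
  if (length(missing))
    stop("genomes present in the map but missing from genomeOrder: ",
         paste(missing, collapse = ", "))
  cl <- clusters(clusterSet)
  m <- matrix(FALSE, nrow = length(cl), ncol = length(genomeOrder),
              dimnames = list(names(cl), genomeOrder))
  for (i in seq_along(cl)) {
    g <- unique(unname(gm[cl[[i]]]))
    m[i, g] <- TRUE
  }
  PresenceAbsence(m)
}

#' Write / read an orthogroup cluster table
#'
#' Tab-separated dialect compatible with common orthogroup tools: a header
#' row `Orthogroup` plus one column per genome; each row lists the
#' cluster's member protein ids per genome, comma-space separated.
#'
#' @param clusterSet an [OrthologClusterSet-class].
#' @param path file path.
#' @param genomeOrder optional column order (default: sorted genomes).
#' @return `writeClusterTable` returns `path` invisibly; `readClusterTable`
#'   an [OrthologClusterSet-class].
#' @export
writeClusterTable <- function(clusterSet, path, genomeOrder = NULL) {
  gm <- genomeMap(clusterSet)
  if (!length(gm)) stop("clusterSet has no genome map")
  if (is.null(genomeOrder)) genomeOrder <- sort(unique(unname(gm)))
  cl <- clusters(clusterSet)
  rows <- lapply(cl, function(members) {
    vapply(genomeOrder, function(g)
      paste(sort(members[gm[members] == g]), collapse = ", "), character(1))
  })
  df <- data.frame(Orthogroup = names(cl),
                   do.call(rbind, rows), check.names = FALSE)
  colnames(df) <- c("Orthogroup", genomeOrder)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusterTable
#' @export
readClusterTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "")
  if (names(df)[1] != "Orthogroup")
    stop("cluster table must start with an 'Orthogroup' column")
  genomes <- names(df)[-1]
  cl <- list(); gm <- character()
  for (r in seq_len(nrow(df))) {
    members <- character()
    for (g in genomes) {
      ids <- strsplit(df[r, g], ",[ ]*")[[1]]
      ids <- ids[nzchar(ids)]
      if (length(ids)) {
        members <- c(members, ids)
        gm[ids] <- g
      }
    }
    cl[[df$Orthogroup[r]]] <- sort(members)
  }
  new("OrthologClusterSet", clusters = cl, genomeMap = gm, converged = TRUE)
}
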