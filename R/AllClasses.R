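#' @import methods
#' @importFrom stats median rpois rnorm runif sd lm coef nls optimize setNames
#' @importFrom utils read.table write.table count.fields head read.csv packageVersion
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet pairwiseAlignment
NULL

#' PresenceAbsence: gene-family by genome incidence matrix
#'
#' The pivot of a pan-genome analysis: a logical matrix with one row per
#' gene family and one column per genome; a cell is `TRUE` when at least one
#' member of the family is encoded by that genome (paralogs collapse to a
#' single presence).
#'
#' Validity requires unique family and genome identifiers and forbids
#' all-absent rows: a family with no genome would be unobservable.
#'
#' @slot incidence logical matrix, families x genomes, dimnames set.
#' @export
setClass("PresenceAbsence", representation(incidence = "matrix"))

setValidity("PresenceAbsence", function(object) {
  m <- object@incidence
  if (!is.logical(m)) return("incidence must be a logical matrix")
  if (is.null(rownames(m)) && nrow(m) > 0) return("family ids (rownames) required")
  if (is.null(colnames(m))) return("genome ids (colnames) required")
  if (anyDuplicated(colnames(m))) return("genome ids must be unique")
  if (nrow(m) > 0 && anyDuplicated(rownames(m))) return("family ids must be unique")
  if (nrow(m) > 0 && any(rowSums(m) == 0))
    return("all-absent rows are not allowed: every family must occur in >= 1 genome")
  if (any(is.na(m))) return("incidence cells must be TRUE/FALSE, not NA")
  TRUE
})

#' SimilarityGraph: weighted undirected protein similarity graph
#'
#' Nodes are protein identifiers; edges carry a positive finite similarity
#' weight (by default a capped \eqn{-\log_{10}} e-value, or a bit score, or a
#' global-alignment score). Self-loops are never stored; Markov clustering
#' adds its own regularizing loops. An optional protein-to-genome map travels
#' with the graph so clusters can later be projected onto genomes.
#'
#' @slot nodes character vector of protein ids.
#' @slot edges data.frame with columns `from`, `to`, `weight` (one row per
#'   undirected edge, `from` < `to` lexicographically).
#' @slot cutoff numeric, the significance cutoff applied at construction.
#' @slot genomeMap named character vector protein id -> genome id (may be
#'   empty when unknown).
#' @export
setClass("SimilarityGraph", representation(
  nodes = "character", edges = "data.frame",
  cutoff = "numeric", genomeMap = "character"))

setValidity("SimilarityGraph", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges needs columns from, to, weight")
  if (nrow(e) > 0) {
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      return("edge weights must be finite and positive")
    if (!all(c(e$from, e$to) %in% object@nodes))
      return("edge endpoints must be listed in nodes")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) return("duplicate undirected edges")
  }
  if (anyDuplicated(object@nodes)) return("node ids must be unique")
  if (length(object@genomeMap) && is.null(names(object@genomeMap)))
    return("genomeMap must be named by protein id")
  TRUE
})

#' OrthologClusterSet: a partition of proteins into gene families
#'
#' Clusters are disjoint sets of protein identifiers whose union covers every
#' input protein (isolated proteins appear as singleton clusters), together
#' with a protein-to-genome map.
#'
#' @slot clusters named list of character vectors (cluster id -> member
#'   protein ids).
#' @slot genomeMap named character vector protein id -> genome id.
#' @slot converged logical, FALSE when the clustering iteration hit its
#'   iteration cap before the convergence tolerance.
#' @export
setClass("OrthologClusterSet", representation(
  clusters = "list", genomeMap = "character", converged = "logical"))

setValidity("OrthologClusterSet", function(object) {
  members <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(members)) return("clusters must be disjoint")
  if (length(object@genomeMap)) {
    if (is.null(names(object@genomeMap))) return("genomeMap must be named")
    miss <- setdiff(members, names(object@genomeMap))
    if (length(miss))
      return(paste0("proteins missing from genomeMap: ", miss[1], " ..."))
  }
  TRUE
})

#' PanGenomePartition: core / accessory / strain-specific subsets
#'
#' Disjoint classification of gene families: core (present in all genomes),
#' accessory (in at least two but not all), and unique/strain-specific
#' (exactly one genome, with the owning genome recorded). With a single
#' genome every family is formally both core and unique; such families are
#' reported as core and the `degenerate` flag is set.
#'
#' @slot coreIds character, family ids present in every genome.
#' @slot accessoryIds character, family ids in >= 2 but < all genomes.
#' @slot uniqueIds named character: names are family ids, values the owning
#'   genome id.
#' @slot nGenomes integer.
#' @slot degenerate logical, TRUE for the single-genome edge case.
#' @export
setClass("PanGenomePartition", representation(
  coreIds = "character", accessoryIds = "character", uniqueIds = "character",
  nGenomes = "integer", degenerate = "logical"))

setValidity("PanGenomePartition", function(object) {
  ids <- c(object@coreIds, object@accessoryIds, names(object@uniqueIds))
  if (anyDuplicated(ids)) return("subsets must be disjoint")
  if (length(object@uniqueIds) && is.null(names(object@uniqueIds)))
    return("uniqueIds must be named by family id (values = owner genome)")
  TRUE
})

#' PanGenomeProfile: permutation accumulation curves
#'
#' For each random genome ordering (permutation) and prefix size N:
#' `pan(N)` counts distinct families among the first N genomes, `core(N)`
#' counts families present in all first N, and `new(N)` counts families first
#' appearing at position N. The aggregated series (median over permutations
#' by default) is what the curve models are fitted to.
#'
#' @slot perPermutation data.frame with columns `permutation`, `N`, `pan`,
#'   `core`, `new`.
#' @slot summary data.frame with columns `N`, `pan`, `core`, `new`
#'   (aggregated over permutations).
#' @slot nPermutations integer.
#' @slot seed integer seed used for the permutation stream (NA if none).
#' @slot aggregator character, name of the aggregation statistic.
#' @export
setClass("PanGenomeProfile", representation(
  perPermutation = "data.frame", summary = "data.frame",
  nPermutations = "integer", seed = "integer", aggregator = "character"))

#' HeapFit: fitted Heap's-law pan-genome growth model
#'
#' Parameters of \eqn{n = k N^{\gamma}} fitted to a pan-genome accumulation
#' series, with \eqn{\alpha = 1 - \gamma}. The pan-genome is called *open*
#' when \eqn{\alpha < 1} (gene repertoire keeps growing with new genomes) and
#' *closed* when \eqn{\alpha > 1}; `boundary` when \eqn{|\alpha - 1|} is
#' within numerical tolerance.
#'
#' @slot k numeric amplitude.
#' @slot gamma numeric exponent.
#' @slot alpha numeric, exactly `1 - gamma`.
#' @slot openness character, one of "open", "closed", "boundary".
#' @slot rss numeric residual sum of squares on the original scale.
#' @slot method character, "loglog" or "nls".
#' @export
setClass("HeapFit", representation(
  k = "numeric", gamma = "numeric", alpha = "numeric",
  openness = "character", rss = "numeric", method = "character"))

setValidity("HeapFit", function(object) {
  if (!isTRUE(all.equal(object@alpha + object@gamma, 1)))
    return("alpha + gamma must equal 1")
  if (!object@openness %in% c("open", "closed", "boundary"))
    return("openness must be open/closed/boundary")
  TRUE
})

#' ExpDecayFit: fitted offset-exponential decay model
#'
#' Parameters of \eqn{n = k e^{-x/t} + tg\theta} fitted by separable least
#' squares. For a core-genome series the asymptote \eqn{tg\theta} is the
#' stabilization plateau; for a new-genes series it is the expected number of
#' novel genes each additional genome contributes. When the amplitude is
#' numerically zero the decay constant t is arbitrary and the
#' `identifiable` flag is cleared.
#'
#' @slot k numeric amplitude.
#' @slot t numeric decay constant (> 0 when identifiable).
#' @slot tgTheta numeric asymptote.
#' @slot rss numeric residual sum of squares.
#' @slot identifiable logical.
#' @export
setClass("ExpDecayFit", representation(
  k = "numeric", t = "numeric", tgTheta = "numeric",
  rss = "numeric", identifiable = "logical"))

setValidity("ExpDecayFit", function(object) {
  if (object@identifiable && object@t <= 0)
    return("decay constant t must be positive for an identifiable fit")
  TRUE
})
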