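#' Functional-category distribution over a gene subset
#'
#' Percentage of a pan-genome subset (e.g. the core genome) falling into
#' each functional category (COG letter or KEGG class), computed over the
#' genes that carry an annotation: percentage = 100 * (subset genes in
#' category) / (subset genes with any category), rounded to whole percent
#' as such distributions are customarily reported. Genes absent from the
#' annotation table (or with NA category) are excluded from the
#' denominator and returned as a separate unannotated count.
#'
#' @param annotation data.frame with columns `id` and `category`.
#' @param subsetIds character vector of gene/family ids (non-empty).
#' @return data.frame with columns `category`, `count`, `percent`
#'   (descending by count); the number of unannotated subset genes is
#'   attached as attribute `"unannotated"`.
#' @examples
#' ann <- data.frame(id = paste0("g", 1:10),
#'                   category = rep(c("J", "L"), each = 5))
#' categoryDistribution(ann, paste0("g", 1:10))
#' @export
categoryDistribution <- function(annotation, subsetIds) {
  stopifnot(all(c("id", "category") %in% names(annotation)))
  if (length(subsetIds) == 0) stop("subset is empty")
  if (anyDuplicated(annotation$id)) stop("annotation ids must be unique")
  cat <- annotation$category[match(subsetIds, annotation$id)]
  annotated <- !is.na(cat)
  tab <- table(cat[annotated])
  denom <- sum(annotated)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    percent = if (denom > 0) round(100 * as.integer(tab) / denom)
                              else numeric(0))
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unannotated") <- sum(!annotated)
  out
}

#' Trait-gene presence/absence heatmap matrix
#'
#' Extracts the incidence sub-matrix for a requested, ordered list of trait
#' genes (e.g. bacteriocin-encoding gene families). Genes not found in the
#' matrix give all-absent rows with a warning, so a screening list can be
#' applied to any strain panel. Rows present in every genome are flagged
#' conserved (attribute `"conserved"`), the pattern of a trait fixed in the
#' species.
#'
#' @param x a [PresenceAbsence-class] matrix.
#' @param geneIds ordered character vector of gene/family ids (non-empty).
#' @return logical matrix `geneIds` x genomes with attribute `"conserved"`
#'   (character vector of all-present gene ids).
#' @export
presenceHeatmap <- function(x, geneIds) {
  stopifnot(is(x, "PresenceAbsence"))
  if (length(geneIds) == 0) stop("gene list is empty")
  m <- incidence(x)
  out <- matrix(FALSE, nrow = length(geneIds), ncol = ncol(m),
                dimnames = list(geneIds, colnames(m)))
  known <- geneIds %in% rownames(m)
  if (any(!known))
    warning("genes absent from the matrix (all-absent rows): ",
            paste(geneIds[!known], collapse = ", "))
  out[known, ] <- m[geneIds[known], , drop = FALSE]
  attr(out, "conserved") <- geneIds[known][rowSums(out[known, , drop = FALSE]) == ncol(m)]
  out
}

#' Plot a presence/absence heatmap
#'
#' Renders the matrix from [presenceHeatmap()] with `pheatmap` (two-colour,
#' no clustering: rows keep the requested order).
#'
#' @param heat matrix from [presenceHeatmap()].
#' @param ... passed to [pheatmap::pheatmap].
#' @export
plotPresenceHeatmap <- function(heat, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotPresenceHeatmap requires the pheatmap package")
  pheatmap::pheatmap(heat + 0, cluster_rows = FALSE, cluster_cols = FALSE,
                     color = c("#1F3B70", "#C8A227"),
                     legend_breaks = c(0, 1),
                     legend_labels = c("absent", "present"), ...)
}

#' Localization-by-adhesin cross-tabulation
#'
#' Counts, per subcellular localization class, the proteins whose adhesin
#' probability score strictly exceeds `threshold` (default 0.7, the
#' customary high-confidence adhesin call), plus the overall total.
#'
#' @param table data.frame with columns `id`, `localization` (one of CYT,
#'   ME, PSE, SE) and `score` in \[0, 1\].
#' @param threshold adhesin score cutoff; strictly greater-than (default
#'   0.7).
#' @return named integer vector with elements CYT, ME, PSE, SE and `total`.
#' @examples
#' tab <- data.frame(id = paste0("p", 1:4),
#'                   localization = c("SE", "PSE", "CYT", "ME"),
#'                   score = c(0.9, 0.8, 0.71, 0.2))
#' adhesinCrosstab(tab)
#' @export
adhesinCrosstab <- function(table, threshold = 0.7) {
  stopifnot(all(c("id", "localization", "score") %in% names(table)))
  classes <- c("CYT", "ME", "PSE", "SE")
  if (!all(table$localization %in% classes))
    stop("localization classes must be one of: ", paste(classes, collapse = ", "))
  if (any(table$score < 0 | table$score > 1))
    stop("adhesin scores must lie in [0, 1]")
  if (anyDuplicated(table$id)) stop("protein ids must be unique")
  hits <- table[table$score > threshold, , drop = FALSE]
  counts <- vapply(classes, function(cl) sum(hits$localization == cl), integer(1))
  c(counts, total = sum(counts))
}

#' @describeIn adhesinCrosstab counts per localization class over the whole
#'   table (no score filter) — the subcellular localization profile.
#' @export
localizationCounts <- function(table) {
  stopifnot(all(c("id", "localization") %in% names(table)))
  classes <- c("CYT", "ME", "PSE", "SE")
  counts <- vapply(classes, function(cl)
    sum(table$localization == cl), integer(1))
  c(counts, total = sum(counts))
}

#' Score-filtered protein-protein interaction network summary
#'
#' Keeps host-microbe interaction edges whose score is at least `minScore`
#' (a minimum-score filter, default 0.9765), computes node degrees on the
#' bipartite bacterial/human network, and reports the most-connected node
#' on each side (ties broken lexicographically). An empty post-filter
#' network yields an explicit empty summary, not an error.
#'
#' @param edges data.frame with columns `bacterial`, `human`, `score` in
#'   \[0, 1\]; no duplicate pairs.
#' @param minScore minimum interaction score retained (>=, default 0.9765).
#' @return list with `edges` (filtered), `degrees` (data.frame `node`,
#'   `side`, `degree`), `topBacterial`, `topHuman` (NA when empty) and
#'   `nInteractions`.
#' @export
ppiSummary <- function(edges, minScore = 0.9765) {
  stopifnot(all(c("bacterial", "human", "score") %in% names(edges)))
  if (any(edges$score < 0 | edges$score > 1))
    stop("interaction scores must lie in [0, 1]")
  if (anyDuplicated(paste(edges$bacterial, edges$human)))
    stop("duplicate interaction pairs")
  keep <- edges[edges$score >= minScore, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(list(edges = keep,
                degrees = data.frame(node = character(), side = character(),
                                     degree = integer()),
                topBacterial = NA_character_, topHuman = NA_character_,
                nInteractions = 0L))
  }
  degOf <- function(v, side) {
    tab <- table(v)
    data.frame(node = names(tab), side = side, degree = as.integer(tab))
  }
  degrees <- rbind(degOf(keep$bacterial, "bacterial"), degOf(keep$human, "human"))
  degrees <- degrees[order(-degrees$degree, degrees$node), ]
  rownames(degrees) <- NULL
  top <- function(side) {
    d <- degrees[degrees$side == side, ]
    d$node[order(-d$degree, d$node)][1]
  }
  list(edges = keep, degrees = degrees,
       topBacterial = top("bacterial"), topHuman = top("human"),
       nInteractions = nrow(keep))
}
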