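#' Classify gene families into core, accessory and strain-specific subsets
#'
#' A family is *core* when present in every genome, *unique*
#' (strain-specific) when present in exactly one, and *accessory* when
#' present in at least two but not all. The three subsets are disjoint and
#' cover all families. With a single genome every family is formally both
#' core and unique; they are reported as core and the partition is flagged
#' degenerate to preserve disjointness.
#'
#' @param x a [PresenceAbsence-class] matrix.
#' @return a [PanGenomePartition-class].
#' @examples
#' m <- rbind(F1 = c(TRUE, TRUE, TRUE), F2 = c(TRUE, TRUE, FALSE),
#'            F3 = c(FALSE, FALSE, TRUE))
#' colnames(m) <- paste0("g", 1:3)
#' panGenomePartition(PresenceAbsence(m))
#' @export
panGenomePartition <- function(x) {
  stopifnot(is(x, "PresenceAbsence"))
  m <- incidence(x)
  nG <- ncol(m)
  if (nG < 1) stop("at least one genome is required")
  occ <- rowSums(m)
  if (nG == 1) {
    return(new("PanGenomePartition", coreIds = rownames(m) %||% character(),
               accessoryIds = character(), uniqueIds = setNames(character(), character()),
               nGenomes = 1L, degenerate = TRUE))
  }
  core <- rownames(m)[occ == nG]
  uniq <- which(occ == 1)
  owner <- colnames(m)[apply(m[uniq, , drop = FALSE], 1L, which.max)]
  uniqueIds <- setNames(owner, rownames(m)[uniq])
  accessory <- rownames(m)[occ > 1 & occ < nG]
  new("PanGenomePartition", coreIds = core, accessoryIds = accessory,
      uniqueIds = uniqueIds, nGenomes = as.integer(nG), degenerate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn panGenomePartition subset counts plus the pan-genome total.
#' @param partition a PanGenomePartition.
#' @export
partitionCounts <- function(partition) {
  stopifnot(is(partition, "PanGenomePartition"))
  c(core = length(partition@coreIds),
    accessory = length(partition@accessoryIds),
    unique = length(partition@uniqueIds),
    total = length(partition@coreIds) + length(partition@accessoryIds) +
      length(partition@uniqueIds))
}

#' @describeIn panGenomePartition per-genome counts of strain-specific
#'   families (named by genome, descending).
#' @export
uniqueCountsPerGenome <- function(partition) {
  stopifnot(is(partition, "PanGenomePartition"))
  tab <- table(unname(partition@uniqueIds))
  sort(setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}

#' Subset percentages under the truncation convention
#'
#' Reports 100 * count / total truncated (not rounded) to two decimals —
#' the convention under which 449/2609 prints as 17.20 rather than the
#' rounded 17.21.
#'
#' @param partition a [PanGenomePartition-class], or a named vector of
#'   counts (any names; a `total` element, if present, is used as the
#'   denominator, otherwise the counts are summed).
#' @return named numeric vector of percentages per subset.
#' @examples
#' partitionPercentages(c(core = 1268, accessory = 892, unique = 449))
#' @export
partitionPercentages <- function(partition) {
  counts <- if (is(partition, "PanGenomePartition")) {
    partitionCounts(partition)
  } else partition
  if (!is.numeric(counts) || is.null(names(counts)))
    stop("expected a PanGenomePartition or a named count vector")
  total <- if ("total" %in% names(counts)) counts[["total"]] else sum(counts)
  counts <- counts[setdiff(names(counts), "total")]
  if (total <= 0) stop("total must be positive")
  setNames(truncateDecimals(100 * counts / total, 2L), names(counts))
}

#' @export
setMethod("show", "PanGenomePartition", function(object) {
  cnt <- partitionCounts(object)
  pct <- partitionPercentages(object)
  cat(sprintf("PanGenomePartition over %d genomes: %d gene families\n",
              object@nGenomes, cnt[["total"]]))
  cat(sprintf("  core %d (%.2f%%) | accessory %d (%.2f%%) | unique %d (%.2f%%)\n",
              cnt[["core"]], pct[["core"]], cnt[["accessory"]], pct[["accessory"]],
              cnt[["unique"]], pct[["unique"]]))
  if (object@degenerate)
    cat("  note: single genome - degenerate pan-genome, families reported as core\n")
  invisible(object)
})

#' Write a partition report TSV
#'
#' One row per family: `subset`, `family`, and for strain-specific families
#' the `owner_genome`.
#'
#' @param partition a [PanGenomePartition-class].
#' @param path file path.
#' @export
writePartitionReport <- function(partition, path) {
  df <- rbind(
    data.frame(subset = "core", family = partition@coreIds,
               owner_genome = NA_character_),
    data.frame(subset = "accessory", family = partition@accessoryIds,
               owner_genome = NA_character_),
    data.frame(subset = "unique", family = names(partition@uniqueIds),
               owner_genome = unname(partition@uniqueIds)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Summary statistics for a genome features table
#'
#' Arithmetic mean and population standard deviation (divisor n) of genome
#' size, GC content and CDS count across strains — the descriptive
#' statistics customarily quoted for a strain panel.
#'
#' @param table data.frame with columns `strain`, `size_mb`, `gc_percent`,
#'   `cds`.
#' @return data.frame with columns `feature`, `mean`, `sd`.
#' @examples
#' tab <- readGenomeSummary(system.file("extdata",
#'   "ldelbrueckii_genome_summary.csv", package = "pangenomics"))
#' genomeSummaryStats(tab)
#' @export
genomeSummaryStats <- function(table) {
  need <- c("strain", "size_mb", "gc_percent", "cds")
  if (!all(need %in% names(table)))
    stop("genome summary table needs columns: ", paste(need, collapse = ", "))
  if (nrow(table) == 0) stop("empty genome summary table")
  if (any(table$size_mb <= 0)) stop("genome sizes must be positive")
  if (any(table$gc_percent <= 0 | table$gc_percent >= 100))
    stop("GC percentages must lie in (0, 100)")
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  feats <- c(size_mb = "size_mb", gc_percent = "gc_percent", cds = "cds")
  data.frame(
    feature = names(feats),
    mean = vapply(feats, function(f) mean(table[[f]]), numeric(1)),
    sd = vapply(feats, function(f) popSd(table[[f]]), numeric(1)),
    row.names = NULL)
}

#' @rdname genomeSummaryStats
#' @param path CSV file with the columns above.
#' @export
readGenomeSummary <- function(path) {
  read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
}
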