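#' Run the pan-genome analysis pipeline end to end
#'
#' Executes the stages cluster -> partition -> curves -> fits -> profiles in
#' order, skipping stages whose inputs are supplied precomputed, and writes
#' a report bundle (tables plus a JSON run manifest) under `outputDir`.
#' Identical configuration and inputs produce byte-identical outputs: all
#' randomness is driven by the mandatory `seed`, and the manifest records a
#' hash of the configuration and of every input file.
#'
#' The gene-family stage resolves its input in precedence order:
#' a precomputed presence/absence TSV (`inputs$presence_absence`), a
#' precomputed orthogroup table (`inputs$cluster_table`), per-genome protein
#' FASTA files (`inputs$proteins`, a directory; genome id = file stem) which
#' are clustered with the built-in scorer plus Markov clustering, an
#' all-vs-all similarity table (`inputs$similarity_table`, with optional
#' `inputs$genome_map` TSV protein→genome), or a synthetic simulation block
#' (`simulate`).
#'
#' @param config a configuration list, or the path to a YAML file holding
#'   one. Recognized top-level keys: `seed` (integer, mandatory when any
#'   stochastic stage runs), `simulate` (n_genomes, core_size, accessory
#'   list of frequency/count pairs, unique_rate), `inputs`
#'   (presence_absence, cluster_table, proteins, similarity_table,
#'   genome_map, genome_summary, annotations (named list of id/category
#'   TSVs), localization, ppi, trait_genes), and `params` (permutations,
#'   evalue_cutoff, adhesin_threshold, ppi_min_score, mcl:
#'   expansion/inflation/prune_threshold/max_iterations/convergence_tol).
#' @param outputDir output directory; tables are written under
#'   `tables/` and the manifest at `manifest.json`.
#' @return invisibly, a list with the in-memory stage results (`matrix`,
#'   `partition`, `profile`, `fits`, `profiles`) and `manifest`.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(outputDir)) outputDir <- config$output_dir
  if (is.null(outputDir)) stop("an output directory is required")
  tablesDir <- file.path(outputDir, "tables")
  dir.create(tablesDir, showWarnings = FALSE, recursive = TRUE)

  params <- config$params %||% list()
  permutations <- params$permutations %||% 100L
  seed <- config$seed
  inputs <- config$inputs %||% list()
  stages <- list()
  inputFiles <- character()
  noteInput <- function(path) inputFiles[[path]] <<- unname(tools::md5sum(path))
  results <- list()

  # --- stage 1: gene families ------------------------------------------------
  if (!is.null(inputs$presence_absence)) {
    noteInput(inputs$presence_absence)
    pa <- readPresenceAbsence(inputs$presence_absence)
    stages$cluster <- "imported (presence/absence matrix)"
  } else if (!is.null(inputs$cluster_table)) {
    noteInput(inputs$cluster_table)
    cs <- readClusterTable(inputs$cluster_table)
    pa <- clustersToMatrix(cs, sort(unique(unname(genomeMap(cs)))))
    results$clusters <- cs
    stages$cluster <- "imported (orthogroup table)"
  } else if (!is.null(inputs$proteins)) {
    faa <- sort(list.files(inputs$proteins, pattern = "\\.(faa|fa|fasta)$",
                           full.names = TRUE))
    if (!length(faa)) stop("no FASTA files found under ", inputs$proteins)
    for (f in faa) noteInput(f)
    sets <- lapply(faa, Biostrings::readAAStringSet)
    gm <- unlist(lapply(seq_along(faa), function(i)
      setNames(rep(sub("\\.[^.]*$", "", basename(faa[i])), length(sets[[i]])),
               names(sets[[i]]))))
    proteins <- do.call(c, sets)
    graph <- computeSimilarities(proteins, genomeMap = gm)
    mclp <- params$mcl %||% list()
    cs <- mclCluster(graph,
                     expansion = mclp$expansion %||% 2L,
                     inflation = mclp$inflation %||% 2,
                     pruneThreshold = mclp$prune_threshold %||% 1e-5,
                     maxIterations = mclp$max_iterations %||% 100L,
                     convergenceTol = mclp$convergence_tol %||% 1e-6)
    writeClusterTable(cs, file.path(tablesDir, "orthogroups.tsv"))
    pa <- clustersToMatrix(cs, sort(unique(unname(gm))))
    results$clusters <- cs
    stages$cluster <- "run (built-in scorer + Markov clustering)"
  } else if (!is.null(inputs$similarity_table)) {
    noteInput(inputs$similarity_table)
    gm <- character()
    if (!is.null(inputs$genome_map)) {
      noteInput(inputs$genome_map)
      gmdf <- read.table(inputs$genome_map, sep = "\t", header = FALSE,
                         col.names = c("protein", "genome"),
                         colClasses = "character")
      gm <- setNames(gmdf$genome, gmdf$protein)
    }
    graph <- readSimilarityTable(inputs$similarity_table,
                                 cutoff = params$evalue_cutoff %||% 1e-5,
                                 genomeMap = gm)
    mclp <- params$mcl %||% list()
    cs <- mclCluster(graph,
                     expansion = mclp$expansion %||% 2L,
                     inflation = mclp$inflation %||% 2,
                     pruneThreshold = mclp$prune_threshold %||% 1e-5,
                     maxIterations = mclp$max_iterations %||% 100L,
                     convergenceTol = mclp$convergence_tol %||% 1e-6)
    writeClusterTable(cs, file.path(tablesDir, "orthogroups.tsv"))
    pa <- clustersToMatrix(cs, sort(unique(unname(genomeMap(cs)))))
    results$clusters <- cs
    stages$cluster <- "run (imported similarity table + Markov clustering)"
  } else if (!is.null(config$simulate)) {
    if (is.null(seed)) stop("seed is mandatory when simulating")
    sim <- config$simulate
    acc <- NULL
    if (!is.null(sim$accessory)) {
      acc <- do.call(rbind, lapply(sim$accessory, function(a)
        data.frame(frequency = a$frequency, count = a$count)))
    }
    simOut <- simulatePanGenome(sim$n_genomes, sim$core_size, accessory = acc,
                                uniqueRate = sim$unique_rate %||% 0,
                                seed = seed)
    pa <- simOut$matrix
    results$truth <- simOut$truth
    write.table(simOut$truth, file.path(tablesDir, "simulation_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    stages$cluster <- "run (synthetic simulation)"
  } else {
    stop("no gene-family input: supply inputs$presence_absence, ",
         "inputs$cluster_table, inputs$proteins, inputs$similarity_table ",
         "or a simulate block")
  }
  writePresenceAbsence(pa, file.path(tablesDir, "presence_absence.tsv"))
  results$matrix <- pa

  # --- stage 2: partition ----------------------------------------------------
  part <- panGenomePartition(pa)
  writePartitionReport(part, file.path(tablesDir, "partition.tsv"))
  cnt <- partitionCounts(part)
  pct <- partitionPercentages(part)
  venn <- data.frame(subset = names(cnt), count = as.integer(cnt),
                     percent = c(pct, total = 100))
  write.table(venn, file.path(tablesDir, "venn_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  results$partition <- part
  stages$partition <- "run"

  # --- stage 3 + 4: curves and fits ------------------------------------------
  if (ncol(incidence(pa)) >= 2) {
    if (is.null(seed)) stop("seed is mandatory for the permutation stage")
    profile <- panCoreCurves(pa, nPermutations = permutations, seed = seed)
    writeCurveTable(profile, file.path(tablesDir, "curves.tsv"))
    results$profile <- profile
    stages$curves <- sprintf("run (%d permutations)", permutations)

    s <- profileSummary(profile)
    heap <- fitHeaps(data.frame(N = s$N, n = s$pan))
    coreFit <- fitExpDecay(data.frame(x = s$N, n = s$core))
    newFit <- if (nrow(s) >= 4)
      fitExpDecay(data.frame(x = s$N[-1], n = s$new[-1])) else NULL
    writeFitReport(heap, coreFit, newFit, file.path(tablesDir, "fit_report"))
    results$fits <- list(heap = heap, core = coreFit, new = newFit,
                         stabilization = if (!is.null(newFit))
                           stabilizationSummary(coreFit, newFit) else NULL)
    stages$fits <- "run"
  } else {
    stages$curves <- "skipped (single genome)"
    stages$fits <- "skipped (single genome)"
  }

  # --- stage 5: annotation profiles ------------------------------------------
  profiles <- list()
  if (!is.null(inputs$annotations)) {
    subsetIds <- list(core = part@coreIds, accessory = part@accessoryIds,
                      unique = names(part@uniqueIds))
    for (nm in names(inputs$annotations)) {
      noteInput(inputs$annotations[[nm]])
      ann <- read.table(inputs$annotations[[nm]], sep = "\t", header = TRUE,
                        colClasses = "character")
      for (sub in names(subsetIds)) {
        if (!length(subsetIds[[sub]])) next
        d <- categoryDistribution(ann, subsetIds[[sub]])
        write.table(d, file.path(tablesDir,
                                 sprintf("%s_distribution_%s.tsv", nm, sub)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        profiles[[paste(nm, sub, sep = "_")]] <- d
      }
    }
  }
  if (!is.null(inputs$trait_genes)) {
    noteInput(inputs$trait_genes)
    genes <- readLines(inputs$trait_genes)
    genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
    heat <- suppressWarnings(presenceHeatmap(pa, genes))
    write.table(data.frame(gene = rownames(heat), heat + 0L,
                           check.names = FALSE),
                file.path(tablesDir, "trait_heatmap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    profiles$traitHeatmap <- heat
  }
  if (!is.null(inputs$localization)) {
    noteInput(inputs$localization)
    loc <- read.table(inputs$localization, sep = "\t", header = TRUE,
                      colClasses = c("character", "character", "numeric"))
    ct <- adhesinCrosstab(loc, threshold = params$adhesin_threshold %||% 0.7)
    lc <- localizationCounts(loc)
    write.table(data.frame(class = names(ct), adhesin = as.integer(ct),
                           all = as.integer(lc)),
                file.path(tablesDir, "adhesin_crosstab.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    profiles$adhesin <- ct
    profiles$localization <- lc
  }
  if (!is.null(inputs$ppi)) {
    noteInput(inputs$ppi)
    ppi <- read.table(inputs$ppi, sep = "\t", header = TRUE,
                      colClasses = c("character", "character", "numeric"))
    ps <- ppiSummary(ppi, minScore = params$ppi_min_score %||% 0.9765)
    write.table(ps$degrees, file.path(tablesDir, "ppi_degrees.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ps$edges, file.path(tablesDir, "ppi_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    profiles$ppi <- ps
  }
  if (!is.null(inputs$genome_summary)) {
    noteInput(inputs$genome_summary)
    gs <- genomeSummaryStats(readGenomeSummary(inputs$genome_summary))
    write.table(gs, file.path(tablesDir, "genome_summary_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    profiles$genomeSummary <- gs
  }
  stages$profile <- if (length(profiles)) "run" else "skipped (no annotation inputs)"
  results$profiles <- profiles

  # --- manifest ---------------------------------------------------------------
  cfgFile <- tempfile(fileext = ".json")
  cfgForHash <- config
  cfgForHash$output_dir <- NULL   # hash analysis parameters, not the destination
  jsonlite::write_json(cfgForHash, cfgFile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "pangenomics",
    version = as.character(utils::packageVersion("pangenomics")),
    seed = seed %||% NA,
    config_md5 = unname(tools::md5sum(cfgFile)),
    inputs = as.list(inputFiles),
    stages = stages)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}
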