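paFrom <- function(m, genomes = paste0("g", seq_len(ncol(m)))) {
  colnames(m) <- genomes
  if (is.null(rownames(m))) rownames(m) <- sprintf("F%02d", seq_len(nrow(m)))
  PresenceAbsence(m)
}

test_that("three-genome toy matrix partitions as expected", {
  pa <- paFrom(rbind(F1 = c(TRUE, TRUE, TRUE),
                     F2 = c(TRUE, TRUE, FALSE),
                     F3 = c(FALSE, FALSE, TRUE)))
  p <- panGenomePartition(pa)
  expect_equal(partitionCounts(p),
               c(core = 1L, accessory = 1L, unique = 1L, total = 3L))
  expect_equal(uniqueCountsPerGenome(p), c(g3 = 1L))
  expect_equal(unname(p@uniqueIds["F3"]), "g3")
})

test_that("random matrices agree with brute-force row-sum classification", {
  set.seed(123)
  for (rep in 1:5) {
    m <- matrix(runif(50 * 5) < 0.5, 50, 5)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    pa <- paFrom(m)
    p <- panGenomePartition(pa)
    occ <- rowSums(incidence(pa))
    expect_equal(length(p@coreIds), sum(occ == 5))
    expect_equal(length(p@accessoryIds), sum(occ > 1 & occ < 5))
    expect_equal(length(p@uniqueIds), sum(occ == 1))
    cnt <- partitionCounts(p)
    expect_equal(cnt[["total"]], nrow(incidence(pa)))
    expect_equal(sum(uniqueCountsPerGenome(p)), cnt[["unique"]])
  }
})

test_that("partition is invariant to row and column order", {
  sim <- simulatePanGenome(6, 15,
    accessory = data.frame(frequency = c(2, 4), count = c(5, 5)),
    uniqueRate = 2, seed = 55)
  m <- incidence(sim$matrix)
  p1 <- panGenomePartition(PresenceAbsence(m))
  set.seed(1)
  m2 <- m[sample(nrow(m)), sample(ncol(m))]
  p2 <- panGenomePartition(PresenceAbsence(m2))
  expect_setequal(p1@coreIds, p2@coreIds)
  expect_setequal(p1@accessoryIds, p2@accessoryIds)
  expect_equal(p1@uniqueIds[sort(names(p1@uniqueIds))],
               p2@uniqueIds[sort(names(p2@uniqueIds))])
})

test_that("partition recovers synthetic truth labels exactly", {
  sim <- simulatePanGenome(7, 25,
    accessory = data.frame(frequency = c(2, 3, 6), count = c(6, 4, 3)),
    uniqueRate = 3, seed = 77)
  p <- panGenomePartition(sim$matrix)
  truth <- sim$truth
  expect_setequal(p@coreIds, truth$family[truth$class == "core"])
  expect_setequal(p@accessoryIds, truth$family[truth$class == "accessory"])
  expect_setequal(names(p@uniqueIds), truth$family[truth$class == "unique"])
  uni <- truth[truth$class == "unique", ]
  expect_equal(unname(p@uniqueIds[uni$family]), uni$genome)
})

test_that("dropping a genome with no private absences cannot shrink the core", {
  sim <- simulatePanGenome(5, 30,
    accessory = data.frame(frequency = c(2, 4), count = c(5, 5)),
    uniqueRate = 0, seed = 9)
  m <- incidence(sim$matrix)
  coreFull <- length(panGenomePartition(PresenceAbsence(m))@coreIds)
  for (g in seq_len(ncol(m))) {
    m2 <- m[, -g, drop = FALSE]
    m2 <- m2[rowSums(m2) > 0, , drop = FALSE]
    coreDrop <- length(panGenomePartition(PresenceAbsence(m2))@coreIds)
    expect_gte(coreDrop, coreFull)
  }
})

test_that("all-absent rows are rejected at construction", {
  m <- rbind(F1 = c(TRUE, TRUE), F2 = c(FALSE, FALSE))
  colnames(m) <- c("g1", "g2")
  expect_error(PresenceAbsence(m), "all-absent")
})

test_that("single-genome matrices are degenerate all-core", {
  pa <- paFrom(matrix(TRUE, 7, 1))
  p <- panGenomePartition(pa)
  expect_true(p@degenerate)
  expect_equal(partitionCounts(p),
               c(core = 7L, accessory = 0L, unique = 0L, total = 7L))
})

test_that("percentages are truncated, not rounded, to two decimals", {
  pct <- partitionPercentages(c(core = 1268, accessory = 892, unique = 449))
  expect_equal(unname(pct), c(48.60, 34.18, 17.20))
  # rounding would have printed 34.19 and 17.21
  expect_equal(unname(partitionPercentages(c(a = 0, b = 10))[["a"]]), 0)
  expect_error(partitionPercentages(c(a = 0, b = 0)), "positive")
})

test_that("genome summary statistics use population SD at table precision", {
  tab <- readGenomeSummary(system.file("extdata",
    "ldelbrueckii_genome_summary.csv", package = "pangenomics"))
  s <- genomeSummaryStats(tab)
  expect_equal(round(s$mean[s$feature == "size_mb"], 3), 1.951)
  expect_equal(round(s$sd[s$feature == "size_mb"], 2), 0.10)
  expect_equal(round(s$mean[s$feature == "gc_percent"], 2), 49.69)
  expect_equal(round(s$sd[s$feature == "gc_percent"], 2), 0.12)
  one <- data.frame(strain = "s", size_mb = 2, gc_percent = 50, cds = 1700)
  s1 <- genomeSummaryStats(one)
  expect_equal(s1$mean, c(2, 50, 1700))
  expect_equal(s1$sd, c(0, 0, 0))
})

test_that("presence/absence TSV round-trips", {
  sim <- simulatePanGenome(4, 8, uniqueRate = 1, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePresenceAbsence(sim$matrix, path)
  back <- readPresenceAbsence(path)
  expect_equal(incidence(back), incidence(sim$matrix))
})
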