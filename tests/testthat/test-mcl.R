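# fixed weighted 10-node graph with three natural communities
fixtureGraph <- function() {
  data.frame(
    from = c("n01", "n01", "n02", "n03", "n01", "n05", "n05", "n06", "n07",
             "n05", "n04", "n08", "n09", "n08"),
    to   = c("n02", "n03", "n03", "n04", "n04", "n06", "n07", "n07", "n08",
             "n08", "n05", "n09", "n10", "n10"),
    weight = c(5, 4, 6, 1, 3, 5, 6, 4, 1, 0.5, 0.5, 5, 4, 6))
}

fixtureAdjacency <- function(ed) {
  ids <- sort(unique(c(ed$from, ed$to)))
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(ed))) {
    adj[ed$from[r], ed$to[r]] <- ed$weight[r]
    adj[ed$to[r], ed$from[r]] <- ed$weight[r]
  }
  adj
}

test_that("disjoint cliques cluster to themselves and isolates stay singletons", {
  ed <- data.frame(from = c("a", "a", "b", "d", "d", "e"),
                   to = c("b", "c", "c", "e", "f", "f"), weight = 1)
  g <- newSimilarityGraphFromEdges(ed, nodes = "zzz")  # plus one isolated node
  cl <- clusters(mclCluster(g))
  expect_equal(cl[order(names(cl))],
               list(a = c("a", "b", "c"), d = c("d", "e", "f"), zzz = "zzz"))
})

test_that("partition matches an independent reference MCL on fixture graphs", {
  ed <- fixtureGraph()
  got <- clusters(mclCluster(newSimilarityGraphFromEdges(ed)))
  ref <- referenceMCL(fixtureAdjacency(ed))
  expect_equal(unname(got[order(vapply(got, `[`, character(1), 1))]),
               lapply(ref, sort)[order(vapply(ref, min, character(1)))])
})

test_that("clusters never span disconnected components", {
  sim <- simulateProteinFamilies(rep(3, 4), seedLength = 100,
                                 substitutionRate = 0.05, seed = 31)
  g <- computeSimilarities(sim$proteins)
  cl <- clusters(mclCluster(g))
  # component id per node from the raw graph (independent flood fill)
  adj <- fixtureAdjacency(edges(g))
  compOf <- setNames(rep(NA_integer_, length(nodes(g))), nodes(g))
  cur <- 0L
  for (v in nodes(g)) {
    if (!is.na(compOf[v])) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(compOf[u])) next
      compOf[u] <- cur
      if (u %in% rownames(adj))
        stack <- c(stack, rownames(adj)[adj[u, ] > 0 & is.na(compOf[rownames(adj)])])
    }
  }
  for (members in cl) expect_length(unique(compOf[members]), 1L)
})

test_that("columns stay stochastic after every inflation step", {
  for (inf in c(1.5, 2, 4)) {
    res <- mclCluster(newSimilarityGraphFromEdges(fixtureGraph()),
                      inflation = inf)
    d <- attr(res, "diagnostics")
    expect_gt(d$iterations, 0)
    expect_lt(d$maxColSumDeviation, 1e-9)
  }
})

test_that("higher inflation never coarsens the fixture partition", {
  g <- newSimilarityGraphFromEdges(fixtureGraph())
  sizes <- vapply(c(1.3, 1.6, 2, 3, 5), function(inf)
    length(clusters(mclCluster(g, inflation = inf))), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("clustering is invariant to input record order", {
  ed <- fixtureGraph()
  g1 <- newSimilarityGraphFromEdges(ed)
  set.seed(3)
  edShuf <- ed[sample(nrow(ed)), ]
  swap <- sample(nrow(edShuf), 5)
  tmp <- edShuf$from[swap]
  edShuf$from[swap] <- edShuf$to[swap]
  edShuf$to[swap] <- tmp
  g2 <- newSimilarityGraphFromEdges(edShuf)
  expect_equal(clusters(mclCluster(g1)), clusters(mclCluster(g2)))
})

test_that("clusters project onto presence/absence with paralog collapse", {
  cs <- new("OrthologClusterSet",
            clusters = list(c1 = c("p1", "p2", "p3"), c2 = "p4"),
            genomeMap = c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g3"),
            converged = TRUE)
  pa <- clustersToMatrix(cs, c("g1", "g2", "g3"))
  expect_equal(incidence(pa),
               rbind(c1 = c(g1 = TRUE, g2 = TRUE, g3 = FALSE),
                     c2 = c(g1 = FALSE, g2 = FALSE, g3 = TRUE)))
  expect_error(clustersToMatrix(cs, c("g1", "g2")), "missing from genomeOrder")
})

test_that("paralog-free matrices survive the matrix -> clusters -> matrix round trip", {
  sim <- simulatePanGenome(4, 6,
    accessory = data.frame(frequency = c(2, 3), count = c(2, 2)),
    uniqueRate = 1, seed = 17)
  m <- incidence(sim$matrix)
  # build one pseudo-protein per presence cell
  gm <- character(); cl <- list()
  for (f in rownames(m)) {
    ids <- paste(f, colnames(m)[m[f, ]], sep = "@")
    gm[ids] <- colnames(m)[m[f, ]]
    cl[[f]] <- ids
  }
  cs <- new("OrthologClusterSet", clusters = cl, genomeMap = gm, converged = TRUE)
  back <- clustersToMatrix(cs, colnames(m))
  expect_equal(incidence(back)[rownames(m), ], m)
})

test_that("cluster tables round-trip through the orthogroup TSV dialect", {
  cs <- new("OrthologClusterSet",
            clusters = list(OG1 = c("g1|a", "g2|b"), OG2 = "g2|c"),
            genomeMap = c("g1|a" = "g1", "g2|b" = "g2", "g2|c" = "g2"),
            converged = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeClusterTable(cs, path)
  back <- readClusterTable(path)
  expect_equal(clusters(back), clusters(cs))
  expect_equal(genomeMap(back)[names(genomeMap(cs))], genomeMap(cs))
})

test_that("end-to-end family recovery from mutated proteins is exact", {
  skip_if_not_installed("mclust")
  fam <- simulateProteinFamilies(rep(4, 5), seedLength = 150,
                                 substitutionRate = 0.02, seed = 11)
  cl <- mclCluster(computeSimilarities(fam$proteins))
  memb <- setNames(rep(seq_along(clusters(cl)), lengths(clusters(cl))),
                   unlist(clusters(cl)))
  ari <- mclust::adjustedRandIndex(memb[fam$truth$protein], fam$truth$family)
  expect_equal(ari, 1.0)
})
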