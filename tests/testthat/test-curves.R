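test_that("identical genomes give flat pan and core curves", {
  m <- matrix(TRUE, 12, 3, dimnames = list(sprintf("F%02d", 1:12), paste0("g", 1:3)))
  prof <- panCoreCurves(PresenceAbsence(m), nPermutations = 8, seed = 2)
  s <- profileSummary(prof)
  expect_equal(s$pan, rep(12, 3))
  expect_equal(s$core, rep(12, 3))
  expect_equal(s$new, c(12, 0, 0))
})

test_that("single genome profile equals its family count", {
  m <- matrix(TRUE, 7, 1, dimnames = list(paste0("F", 1:7), "g1"))
  prof <- panCoreCurves(PresenceAbsence(m), nPermutations = 1, seed = 1)
  s <- profileSummary(prof)
  expect_equal(s$pan, 7)
  expect_equal(s$core, 7)
})

test_that("per-permutation curves obey monotonicity and the new-gene identity", {
  sim <- simulatePanGenome(6, 20,
    accessory = data.frame(frequency = c(2, 4), count = c(8, 6)),
    uniqueRate = 3, seed = 13)
  prof <- panCoreCurves(sim$matrix, nPermutations = 25, seed = 13)
  per <- prof@perPermutation
  for (p in unique(per$permutation)) {
    sub <- per[per$permutation == p, ]
    expect_true(all(diff(sub$pan) >= 0))
    expect_true(all(diff(sub$core) <= 0))
    expect_equal(sum(sub$new), sub$pan[nrow(sub)])
    expect_equal(sub$pan[1], sub$core[1])
  }
})

test_that("exhaustive aggregation equals brute-force enumeration of orderings", {
  sim <- simulatePanGenome(3, 5,
    accessory = data.frame(frequency = 2, count = 3), uniqueRate = 2, seed = 29)
  m <- incidence(sim$matrix)
  prof <- panCoreCurves(sim$matrix, exhaustive = TRUE)
  expect_equal(prof@nPermutations, 6L)

  # independent enumeration over all 3! orderings
  library(utils)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  panMat <- coreMat <- newMat <- matrix(0, 6, 3)
  for (i in seq_along(perms)) {
    ord <- perms[[i]]
    for (N in 1:3) {
      sub <- m[, ord[1:N], drop = FALSE]
      panMat[i, N] <- sum(rowSums(sub) > 0)
      coreMat[i, N] <- sum(rowSums(sub) == N)
    }
    newMat[i, ] <- c(panMat[i, 1], diff(panMat[i, ]))
  }
  s <- profileSummary(prof)
  expect_equal(s$pan, apply(panMat, 2, median))
  expect_equal(s$core, apply(coreMat, 2, median))
  expect_equal(s$new, apply(newMat, 2, median))
})

test_that("median pan curve rises and core curve falls on rich matrices", {
  sim <- simulatePanGenome(8, 60,
    accessory = data.frame(frequency = c(2, 4, 6), count = c(15, 10, 8)),
    uniqueRate = 6, seed = 41)
  s <- profileSummary(panCoreCurves(sim$matrix, nPermutations = 50, seed = 41))
  expect_true(all(diff(s$pan) > 0))
  expect_true(all(diff(s$core) <= 0))
  expect_true(any(diff(s$core) < 0))
})

test_that("Heap fit recovers printed and exact power-law parameters", {
  pts <- simulateCurveData("heap", list(k = 1848.134, gamma = 0.156), 1:9)
  fit <- fitHeaps(pts)
  expect_equal(fit@gamma, 0.156, tolerance = 1e-6)
  expect_equal(fit@alpha, 0.844, tolerance = 1e-6)
  expect_equal(openness(fit), "open")

  lin <- fitHeaps(data.frame(N = 1:9, n = 5 * (1:9)))
  expect_equal(unname(heapParameters(lin)), c(5, 1, 0), tolerance = 1e-9)
  expect_equal(openness(lin), "open")

  flat <- fitHeaps(data.frame(N = 1:9, n = rep(100, 9)))
  expect_equal(flat@gamma, 0, tolerance = 1e-12)
  expect_equal(openness(flat), "boundary")

  expect_error(fitHeaps(data.frame(N = 1:3, n = c(1, -1, 2))), "positive")
})

test_that("noise-free Heap recovery holds across a (k, gamma) grid", {
  for (k in c(10, 500, 2000)) for (gamma in c(0, 0.05, 0.3, 0.7, 1)) {
    pts <- simulateCurveData("heap", list(k = k, gamma = gamma), 1:9)
    fit <- fitHeaps(pts)
    expect_equal(fit@k, k, tolerance = 1e-6)
    expect_equal(fit@gamma, gamma, tolerance = 1e-6)
  }
})

test_that("a negative-exponent series is called closed", {
  pts <- simulateCurveData("heap", list(k = 300, gamma = -0.1), 1:9)
  fit <- fitHeaps(pts)
  expect_gt(fit@alpha, 1)
  expect_equal(openness(fit), "closed")
})

test_that("offset-exponential fit recovers the printed decay models", {
  core <- simulateCurveData("expdecay",
    list(k = 465.995, t = 4.839, tgTheta = 1182.675), 1:9)
  fc <- fitExpDecay(core)
  expect_equal(fc@tgTheta, 1182.675, tolerance = 0.5 / 1182.675)
  expect_equal(fc@t, 4.839, tolerance = 1e-3)
  expect_equal(fc@k, 465.995, tolerance = 1e-3)

  uniq <- simulateCurveData("expdecay",
    list(k = 219.676, t = 4.356, tgTheta = 24.813), 1:9)
  fu <- fitExpDecay(uniq)
  expect_equal(fu@tgTheta, 24.813, tolerance = 0.1 / 24.813)
})

test_that("noise-free exponential recovery holds across a parameter grid", {
  for (k in c(50, 400)) for (t in c(0.5, 2, 8, 20)) for (tg in c(10, 1200)) {
    pts <- simulateCurveData("expdecay", list(k = k, t = t, tgTheta = tg), 1:9)
    fit <- fitExpDecay(pts)
    expect_equal(fit@k, k, tolerance = 1e-3)
    expect_equal(fit@t, t, tolerance = 1e-3)
    expect_equal(fit@tgTheta, tg, tolerance = 1e-3)
  }
})

test_that("constant series are flagged unidentifiable with the level as asymptote", {
  fit <- fitExpDecay(data.frame(x = 1:6, n = rep(7, 6)))
  expect_false(fit@identifiable)
  expect_equal(fit@k, 0)
  expect_equal(fit@tgTheta, 7)
  expect_error(fitExpDecay(data.frame(x = 1:2, n = c(1, 2))), "3 points")
  expect_error(fitExpDecay(data.frame(x = rep(1, 4), n = 1:4)), "equal")
})

test_that("fit estimates are unbiased under noise (Monte Carlo)", {
  nRep <- 200
  gammas <- vapply(seq_len(nRep), function(s) {
    pts <- simulateCurveData("heap", list(k = 2000, gamma = 0.2), 1:9,
                             noiseSd = 5, seed = s)
    fitHeaps(pts)@gamma
  }, numeric(1))
  expect_lt(abs(mean(gammas) - 0.2), 3 * sd(gammas) / sqrt(nRep))

  tgs <- vapply(seq_len(nRep), function(s) {
    pts <- simulateCurveData("expdecay",
      list(k = 400, t = 4, tgTheta = 1000), 1:9, noiseSd = 5, seed = 1000 + s)
    fitExpDecay(pts)@tgTheta
  }, numeric(1))
  expect_lt(abs(mean(tgs) - 1000), 3 * sd(tgs) / sqrt(nRep))
})

test_that("stabilization summary reads the asymptotes off the fits", {
  core <- fitExpDecay(simulateCurveData("expdecay",
    list(k = 465.995, t = 4.839, tgTheta = 1182.675), 1:9))
  uniq <- fitExpDecay(simulateCurveData("expdecay",
    list(k = 219.676, t = 4.356, tgTheta = 24.813), 1:9))
  s <- stabilizationSummary(core, uniq)
  expect_equal(s$corePlateauWhole, 1182)
  expect_equal(s$newGenesPerGenomeWhole, 24)
  expect_equal(s$newGenesPerGenome, 24.813, tolerance = 1e-3)

  flat <- fitExpDecay(data.frame(x = 1:5, n = rep(42, 5)))
  s2 <- stabilizationSummary(flat, flat)
  expect_equal(s2$corePlateau, 42)
  expect_false(s2$identifiable[["core"]])
})
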