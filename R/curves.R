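#' Permutation-based pan- and core-genome accumulation curves
#'
#' For each of `nPermutations` uniformly random genome orderings, computes
#' the pan-genome size (distinct families among the first N genomes), the
#' core size (families shared by all first N) and the number of new
#' families first seen at position N, for N = 1..(number of genomes). The
#' aggregated series — the median over permutations by default — is the
#' input to the curve models. Set `exhaustive = TRUE` to enumerate all N!
#' orderings instead of sampling (feasible for small genome panels).
#'
#' @param x a [PresenceAbsence-class] matrix.
#' @param nPermutations number of random orderings (>= 1; default 100).
#' @param seed integer seed for the permutation stream.
#' @param aggregator summary statistic across permutations (default
#'   [stats::median]).
#' @param exhaustive enumerate every genome ordering instead of sampling.
#' @return a [PanGenomeProfile-class].
#' @examples
#' sim <- simulatePanGenome(6, coreSize = 50,
#'   accessory = data.frame(frequency = 2:5, count = 10), uniqueRate = 4,
#'   seed = 7)
#' panCoreCurves(sim$matrix, nPermutations = 20, seed = 7)
#' @export
panCoreCurves <- function(x, nPermutations = 100L, seed = NULL,
                          aggregator = stats::median, exhaustive = FALSE) {
  stopifnot(is(x, "PresenceAbsence"))
  m <- incidence(x)
  nG <- ncol(m)
  aggName <- deparse(substitute(aggregator))
  if (!exhaustive) nPermutations <- assertCount(nPermutations, "nPermutations", 1L)

  orders <- if (exhaustive) {
    perms <- allPermutations(nG)
    nPermutations <- length(perms)
    perms
  } else {
    withSeed(seed, lapply(seq_len(nPermutations),
                          function(i) sample.int(nG)))
  }

  rows <- vector("list", nPermutations)
  for (p in seq_len(nPermutations)) {
    ord <- orders[[p]]
    seen <- rep(FALSE, nrow(m))        # family observed so far
    inAll <- rep(TRUE, nrow(m))        # family present in every prefix genome
    pan <- core <- new <- integer(nG)
    prevPan <- 0L
    for (i in seq_len(nG)) {
      col <- m[, ord[i]]
      seen <- seen | col
      inAll <- inAll & col
      pan[i] <- sum(seen)
      core[i] <- sum(inAll)
      new[i] <- pan[i] - prevPan
      prevPan <- pan[i]
    }
    rows[[p]] <- data.frame(permutation = p, N = seq_len(nG),
                            pan = pan, core = core, new = new)
  }
  per <- do.call(rbind, rows)
  agg <- function(v) tapply(v, per$N, aggregator)
  summary <- data.frame(N = sort(unique(per$N)), pan = as.numeric(agg(per$pan)),
                        core = as.numeric(agg(per$core)),
                        new = as.numeric(agg(per$new)), row.names = NULL)
  new("PanGenomeProfile", perPermutation = per, summary = summary,
      nPermutations = as.integer(nPermutations),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      aggregator = aggName)
}

allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' @describeIn panCoreCurves the aggregated (N, pan, core, new) series.
#' @param profile a PanGenomeProfile.
#' @export
profileSummary <- function(profile) {
  stopifnot(is(profile, "PanGenomeProfile"))
  profile@summary
}

#' @export
setMethod("show", "PanGenomeProfile", function(object) {
  s <- object@summary
  cat(sprintf("PanGenomeProfile: %d permutations (%s aggregate), N = 1..%d\n",
              object@nPermutations, object@aggregator, max(s$N)))
  cat(sprintf("  pan %s -> %s | core %s -> %s\n",
              format(s$pan[1]), format(s$pan[nrow(s)]),
              format(s$core[1]), format(s$core[nrow(s)])))
  invisible(object)
})

#' Write the aggregated accumulation curves as TSV
#'
#' Columns: N, pan, core and new aggregates plus the 25% and 75% quantiles
#' of each statistic across permutations.
#'
#' @param profile a [PanGenomeProfile-class].
#' @param path file path.
#' @export
writeCurveTable <- function(profile, path) {
  per <- profile@perPermutation
  q <- function(v, p) as.numeric(tapply(v, per$N, stats::quantile, probs = p))
  out <- profile@summary
  for (stat in c("pan", "core", "new")) {
    out[[paste0(stat, "_q25")]] <- q(per[[stat]], 0.25)
    out[[paste0(stat, "_q75")]] <- q(per[[stat]], 0.75)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
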