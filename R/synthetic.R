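#' Simulate a pan-genome presence/absence matrix with known truth
#'
#' Generates the incidence structure a pan-genome analysis assumes: a fixed
#' set of core families present in every genome, accessory families each
#' present in a prescribed number of genomes (2 <= f < nGenomes, genomes
#' drawn uniformly without replacement), and per-genome strain-specific
#' (singleton) families with Poisson-distributed counts. The generative
#' model is deliberately exchangeable across genomes: no phylogeny, gene
#' order or linkage.
#'
#' @param nGenomes number of genomes (>= 1).
#' @param coreSize number of core families (>= 0).
#' @param accessory data.frame with columns `frequency` (number of genomes a
#'   family occurs in; each strictly between 1 and `nGenomes`) and `count`
#'   (number of such families), or NULL for none.
#' @param uniqueRate Poisson mean number of strain-specific novel families
#'   per genome (>= 0).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @param genomeIds optional character vector of genome names.
#' @return a list with `matrix` (a [PresenceAbsence-class]) and `truth`, a
#'   data.frame with columns `family`, `class` ("core", "accessory",
#'   "unique") and `genome` (owner, NA except for unique families).
#' @examples
#' sim <- simulatePanGenome(nGenomes = 5, coreSize = 20,
#'   accessory = data.frame(frequency = c(2, 4), count = c(3, 2)),
#'   uniqueRate = 1.5, seed = 42)
#' sim$matrix
#' table(sim$truth$class)
#' @export
simulatePanGenome <- function(nGenomes, coreSize, accessory = NULL,
                              uniqueRate = 0, seed = NULL,
                              genomeIds = NULL) {
  nGenomes <- assertCount(nGenomes, "nGenomes", min = 1L)
  coreSize <- assertCount(coreSize, "coreSize", min = 0L)
  if (!is.null(accessory)) {
    stopifnot(is.data.frame(accessory),
              all(c("frequency", "count") %in% names(accessory)))
    if (any(accessory$frequency <= 1 | accessory$frequency >= nGenomes))
      stop("accessory frequencies must be strictly between 1 and nGenomes")
    if (any(accessory$count < 0)) stop("accessory counts must be >= 0")
  }
  if (length(uniqueRate) != 1 || is.na(uniqueRate) || uniqueRate < 0)
    stop("uniqueRate must be a single nonnegative number")
  if (is.null(genomeIds)) {
    genomeIds <- sprintf("genome%02d", seq_len(nGenomes))
  } else stopifnot(length(genomeIds) == nGenomes, !anyDuplicated(genomeIds))

  withSeed(seed, {
    rows <- list(); classes <- character(); owners <- character()
    famIds <- character()
    if (coreSize > 0) {
      for (i in seq_len(coreSize)) rows[[length(rows) + 1L]] <- rep(TRUE, nGenomes)
      famIds <- c(famIds, sprintf("core%04d", seq_len(coreSize)))
      classes <- c(classes, rep("core", coreSize))
      owners <- c(owners, rep(NA_character_, coreSize))
    }
    if (!is.null(accessory)) {
      idx <- 0L
      for (r in seq_len(nrow(accessory))) {
        f <- accessory$frequency[r]
        for (j in seq_len(accessory$count[r])) {
          present <- rep(FALSE, nGenomes)
          present[sample.int(nGenomes, f)] <- TRUE
          rows[[length(rows) + 1L]] <- present
          idx <- idx + 1L
          famIds <- c(famIds, sprintf("acc%04d", idx))
          classes <- c(classes, "accessory")
          owners <- c(owners, NA_character_)
        }
      }
    }
    if (uniqueRate >= 0) {
      nNew <- rpois(nGenomes, uniqueRate)
      idx <- 0L
      for (g in seq_len(nGenomes)) {
        for (j in seq_len(nNew[g])) {
          present <- rep(FALSE, nGenomes)
          present[g] <- TRUE
          rows[[length(rows) + 1L]] <- present
          idx <- idx + 1L
          famIds <- c(famIds, sprintf("uni%04d", idx))
          classes <- c(classes, "unique")
          owners <- c(owners, genomeIds[g])
        }
      }
    }
    m <- matrix(FALSE, nrow = length(rows), ncol = nGenomes,
                dimnames = list(famIds, genomeIds))
    for (i in seq_along(rows)) m[i, ] <- rows[[i]]
    list(matrix = PresenceAbsence(m),
         truth = data.frame(family = famIds, class = classes,
                            genome = owners, stringsAsFactors = FALSE))
  })
}

#' Simulate accumulation-curve data from a known model
#'
#' Draws (N, n) points from either the Heap's-law power model
#' \eqn{n = k N^{\gamma}} or the offset-exponential decay
#' \eqn{n = k e^{-x/t} + tg\theta}, plus optional i.i.d. Gaussian noise.
#' With `noiseSd = 0` the points lie exactly on the model curve, which is
#' how parameter-recovery checks are seeded.
#'
#' @param model "heap" or "expdecay".
#' @param params named list: `k` and `gamma` for "heap"; `k`, `t`,
#'   `tgTheta` for "expdecay".
#' @param N increasing positive integers (genome numbers / indices).
#' @param noiseSd standard deviation of additive Gaussian noise (>= 0).
#' @param seed integer seed for the noise stream.
#' @return data.frame with columns `N` and `n`.
#' @examples
#' simulateCurveData("heap", list(k = 1848.134, gamma = 0.156), N = 1:9)
#' @export
simulateCurveData <- function(model = c("heap", "expdecay"), params, N,
                              noiseSd = 0, seed = NULL) {
  model <- match.arg(model)
  if (length(N) == 0 || any(N <= 0) || any(diff(N) <= 0))
    stop("N must be non-empty increasing positive values")
  if (length(noiseSd) != 1 || is.na(noiseSd) || noiseSd < 0)
    stop("noiseSd must be a single nonnegative number")
  mu <- switch(model,
    heap = params$k * N^params$gamma,
    expdecay = params$k * exp(-N / params$t) + params$tgTheta)
  n <- withSeed(seed, mu + if (noiseSd > 0) rnorm(length(N), 0, noiseSd) else 0)
  data.frame(N = N, n = n)
}

#' Simulate protein families as mutated copies of seed sequences
#'
#' Each family starts from a random amino-acid seed sequence (uniform over
#' the 20 standard residues); member i of a family is a copy carrying i.i.d.
#' per-site substitutions at `substitutionRate`, each substitution uniform
#' over the 19 alternative residues. Member j of every family is assigned to
#' genome j, so families double as single-copy orthogroups with known truth.
#' No indels are introduced: members stay aligned to the seed.
#'
#' @param familySizes integer vector, number of members per family (>= 1).
#' @param seedLength seed sequence length in residues (> 0).
#' @param substitutionRate per-site substitution probability in \[0, 1\].
#' @param seed integer seed.
#' @return list with `proteins` (a [Biostrings::AAStringSet] whose names are
#'   `<genome>|<family>` protein ids) and `truth`, a data.frame with columns
#'   `protein`, `family`, `genome`.
#' @examples
#' fam <- simulateProteinFamilies(c(3, 2), seedLength = 50,
#'                                substitutionRate = 0.02, seed = 1)
#' fam$proteins
#' @export
simulateProteinFamilies <- function(familySizes, seedLength = 200L,
                                    substitutionRate = 0.02, seed = NULL) {
  if (length(familySizes) == 0) stop("familySizes must be non-empty")
  if (any(familySizes < 1)) stop("family sizes must be >= 1")
  seedLength <- assertCount(seedLength, "seedLength", min = 1L)
  if (substitutionRate < 0 || substitutionRate > 1)
    stop("substitutionRate must be in [0, 1]")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withSeed(seed, {
    seqs <- character(); prot <- character(); fam <- character(); gen <- character()
    for (i in seq_along(familySizes)) {
      template <- sample(aa, seedLength, replace = TRUE)
      famId <- sprintf("fam%03d", i)
      for (j in seq_len(familySizes[i])) {
        s <- template
        hit <- runif(seedLength) < substitutionRate
        if (any(hit)) {
          s[hit] <- vapply(s[hit],
            function(res) sample(setdiff(aa, res), 1L), character(1))
        }
        genomeId <- sprintf("genome%02d", j)
        id <- paste0(genomeId, "|", famId)
        seqs <- c(seqs, paste(s, collapse = ""))
        prot <- c(prot, id); fam <- c(fam, famId); gen <- c(gen, genomeId)
      }
    }
    proteins <- Biostrings::AAStringSet(setNames(seqs, prot))
    list(proteins = proteins,
         truth = data.frame(protein = prot, family = fam, genome = gen,
                            stringsAsFactors = FALSE))
  })
}

#' Write simulated proteins as one FASTA file per genome
#'
#' @param proteins named [Biostrings::AAStringSet] with `<genome>|...` ids.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (named by genome id).
#' @export
writeGenomeFastas <- function(proteins, dir) {
  genomes <- sub("\\|.*$", "", names(proteins))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (g in unique(genomes)) {
    p <- file.path(dir, paste0(g, ".faa"))
    Biostrings::writeXStringSet(proteins[genomes == g], p)
    paths[g] <- p
  }
  invisible(paths)
}
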