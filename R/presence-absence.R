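#' Construct a PresenceAbsence matrix
#'
#' @param incidence logical (or 0/1 numeric) matrix, families in rows,
#'   genomes in columns; dimnames required (row names may be omitted for a
#'   0-row matrix).
#' @return a [PresenceAbsence-class] object.
#' @examples
#' m <- rbind(famA = c(TRUE, TRUE, FALSE), famB = c(TRUE, TRUE, TRUE))
#' colnames(m) <- c("g1", "g2", "g3")
#' PresenceAbsence(m)
#' @export
PresenceAbsence <- function(incidence) {
  if (is.numeric(incidence)) {
    storage.mode(incidence) <- "logical"
  }
  new("PresenceAbsence", incidence = incidence)
}

#' @describeIn PresenceAbsence family identifiers (row names).
#' @param x,object a PresenceAbsence object.
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @export
setMethod("familyIds", "PresenceAbsence", function(x) rownames(x@incidence))

#' @describeIn PresenceAbsence genome identifiers (column names).
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @export
setMethod("genomeIds", "PresenceAbsence", function(x) colnames(x@incidence))

#' @describeIn PresenceAbsence the underlying logical matrix.
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @export
setMethod("incidence", "PresenceAbsence", function(x) x@incidence)

#' @export
setMethod("dim", "PresenceAbsence", function(x) dim(x@incidence))

#' @export
setMethod("show", "PresenceAbsence", function(object) {
  d <- dim(object@incidence)
  cat(sprintf("PresenceAbsence: %d gene families x %d genomes\n", d[1], d[2]))
  if (d[1] > 0) {
    occ <- rowSums(object@incidence)
    cat(sprintf("  core (all %d genomes): %d | accessory: %d | unique: %d\n",
                d[2], sum(occ == d[2] & d[2] > 1) + sum(d[2] == 1 & occ == 1),
                sum(occ > 1 & occ < d[2]), if (d[2] > 1) sum(occ == 1) else 0L))
  }
  invisible(object)
})

#' Write / read a presence-absence matrix as TSV
#'
#' Plain-text dialect: first column `family`, one column per genome, cells
#' `0`/`1`. Round-trips through [readPresenceAbsence()].
#'
#' @param x a PresenceAbsence object.
#' @param path file path.
#' @return `writePresenceAbsence` returns `path` invisibly;
#'   `readPresenceAbsence` returns a [PresenceAbsence-class].
#' @export
writePresenceAbsence <- function(x, path) {
  stopifnot(is(x, "PresenceAbsence"))
  m <- incidence(x)
  df <- data.frame(family = rownames(m), m + 0L, check.names = FALSE)
  if (nrow(m) == 0) df <- setNames(
    data.frame(matrix(nrow = 0, ncol = ncol(m) + 1)), c("family", colnames(m)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePresenceAbsence
#' @export
readPresenceAbsence <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (names(df)[1] != "family")
    stop("presence/absence TSV must start with a 'family' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$family
  PresenceAbsence(m > 0L)
}
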