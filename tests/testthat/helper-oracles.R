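# independent dense MCL: components of the limit-matrix support graph
referenceMCL <- function(adj, expansion = 2, inflation = 2,
                         prune = 1e-5, maxit = 100, tol = 1e-6) {
  n <- nrow(adj)
  ids <- rownames(adj)
  for (i in seq_len(n)) {
    mx <- max(adj[i, ])
    adj[i, i] <- if (mx > 0) mx else 1
  }
  M <- adj
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (iter in seq_len(maxit)) {
    E <- diag(n)
    for (p in seq_len(expansion)) E <- E %*% M
    I <- E^inflation
    I[I < prune] <- 0
    for (j in seq_len(n)) {
      s <- sum(I[, j])
      if (s == 0) { I[j, j] <- 1; s <- 1 }
      I[, j] <- I[, j] / s
    }
    if (max(abs(I - M)) < tol) { M <- I; break }
    M <- I
  }
  supp <- (M > 0) | t(M > 0)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[u])) next
      comp[u] <- cur
      stack <- c(stack, which(supp[u, ] & is.na(comp)))
    }
  }
  unname(split(ids, comp))
}

# independent affine-gap global alignment (Gotoh), gap cost open + L*ext
gotohScore <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[A[i], B[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}
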