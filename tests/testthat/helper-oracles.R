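# Independent oracles: literal implementations used to cross-check the
# package's vectorized/clustered code paths.

# Brute-force TOM: triple loop over the definition.
bruteForceTOM <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  t <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    t[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  t
}

randomAdjacency <- function(n) {
  r <- matrix(runif(n * n), n, n)
  a <- (r + t(r)) / 2
  diag(a) <- 1
  a
}

# Plain-loop reference of the fuzzy C-means update equations.
referenceFCM <- function(x, u, m = 2, tol = 1e-9, maxIter = 500) {
  x <- as.matrix(x)
  for (it in seq_len(maxIter)) {
    um <- u^m
    cent <- lapply(1:ncol(u), function(j)
      colSums(x * um[, j]) / sum(um[, j]))
    d2 <- sapply(cent, function(cj)
      apply(x, 1, function(row) sum((row - cj)^2)))
    uNew <- matrix(0, nrow(x), ncol(u))
    for (k in seq_len(nrow(x))) for (j in seq_len(ncol(u))) {
      if (d2[k, j] < 1e-24) { uNew[k, ] <- 0; uNew[k, j] <- 1; break }
      uNew[k, j] <- 1 / sum((d2[k, j] / d2[k, ])^(1 / (m - 1)))
    }
    if (max(abs(uNew - u)) < tol) { u <- uNew; break }
    u <- uNew
  }
  u
}

# Closed-form Pearson chi-square for a 2x2 table.
closedFormChi <- function(t) {
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
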