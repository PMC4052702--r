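# Independent reference implementations used as oracles. Deliberately
# written in the plainest possible style (explicit loops, scalar sums),
# sharing no code with the package's vectorized paths.

# Textbook PLS1: extract A components from column-wise preprocessed X and
# centered y by the classical deflation recursion, one scalar at a time.
refPls1 <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, A); Tm <- matrix(0, n, A); P <- matrix(0, p, A)
  q <- numeric(A); ssy <- numeric(A)
  Xa <- X; ya <- y
  for (a in 1:A) {
    w <- numeric(p)
    for (j in 1:p) {
      s <- 0
      for (i in 1:n) s <- s + Xa[i, j] * ya[i]
      w[j] <- s
    }
    nw <- 0
    for (j in 1:p) nw <- nw + w[j]^2
    nw <- sqrt(nw)
    for (j in 1:p) w[j] <- w[j] / nw
    t <- numeric(n)
    for (i in 1:n) {
      s <- 0
      for (j in 1:p) s <- s + Xa[i, j] * w[j]
      t[i] <- s
    }
    tt <- 0
    for (i in 1:n) tt <- tt + t[i]^2
    pv <- numeric(p)
    for (j in 1:p) {
      s <- 0
      for (i in 1:n) s <- s + Xa[i, j] * t[i]
      pv[j] <- s / tt
    }
    qa <- 0
    for (i in 1:n) qa <- qa + ya[i] * t[i]
    qa <- qa / tt
    for (i in 1:n) for (j in 1:p) Xa[i, j] <- Xa[i, j] - t[i] * pv[j]
    for (i in 1:n) ya[i] <- ya[i] - qa * t[i]
    W[, a] <- w; Tm[, a] <- t; P[, a] <- pv; q[a] <- qa; ssy[a] <- qa^2 * tt
  }
  yhat <- numeric(n)
  for (i in 1:n) for (a in 1:A) yhat[i] <- yhat[i] + q[a] * Tm[i, a]
  vip <- numeric(p)
  stot <- sum(ssy)
  for (j in 1:p) {
    s <- 0
    for (a in 1:A) s <- s + ssy[a] * W[j, a]^2
    vip[j] <- sqrt(p * s / stot)
  }
  list(W = W, T = Tm, P = P, q = q, ssy = ssy, yhat = yhat, vip = vip)
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe of N genes of which the first K are annotated, and count draws
# with at least k annotated members. Exact for small N (integer counts).
refHyperUpper <- function(N, K, n, k) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- 0
  for (col in seq_len(ncol(draws))) {
    if (sum(draws[, col] <= K) >= k) hits <- hits + 1
  }
  hits / choose(N, n)
}

# Brute-force distinct-neighbor degree count over an edge data.frame.
refDegrees <- function(nodes, edges) {
  deg <- setNames(integer(length(nodes)), nodes)
  for (v in nodes) {
    nb <- character(0)
    for (r in seq_len(nrow(edges))) {
      a <- edges$gene_a[r]; b <- edges$gene_b[r]
      if (a == b) next
      if (a == v) nb <- c(nb, b)
      if (b == v) nb <- c(nb, a)
    }
    deg[v] <- length(unique(nb))
  }
  deg
}
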