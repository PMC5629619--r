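# Shared helpers: tiny matrices built in code and brute-force oracles kept
# independent of the package's internals.

mat <- function(v, nrow, prefix = "S") {
  m <- matrix(v, nrow = nrow, byrow = TRUE)
  dimnames(m) <- list(sprintf("%s%02d", prefix, seq_len(nrow(m))),
                      sprintf("G%02d", seq_len(ncol(m))))
  m
}

# all pairwise Euclidean distances, the slow way
bruteDist <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      out[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  out
}

# brute-force pairwise AUC with half credit for ties
bruteAUC <- function(scores, labels, positive = 1L) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# leverage scores via an eigendecomposition of the Gram matrix, independent
# of svd()
bruteLeverage <- function(M, l) {
  eg <- eigen(crossprod(M), symmetric = TRUE)
  V <- eg$vectors[, seq_len(l), drop = FALSE]
  rowSums(V^2) / l
}

# ordinary least squares through the normal equations (alpha -> 0 ridge limit)
bruteOLS <- function(X, y) {
  Xi <- cbind(1, X)
  as.numeric(solve(crossprod(Xi), crossprod(Xi, y)))
}

expect_setequal_int <- function(a, b) expect_setequal(as.integer(a), as.integer(b))
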