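## Column selection by CUR normalized statistical leverage scores. Only the
## scores and the selected index set are needed downstream, so the C, U, R
## factors of the decomposition are never materialized: the score of column j
## is the mean squared mass of its entries across the top-l right singular
## vectors.

#' Normalized statistical leverage scores of feature columns
#'
#' Computes the top-\code{l} right singular vectors of \code{M} and scores
#' column j as \code{pi_j = (1/l) * sum_xi (v_j^xi)^2}. Scores are
#' nonnegative and sum to 1; a high score marks an influential column.
#' Deterministic truncated SVD (no randomized sketching).
#'
#' @param M numeric matrix, samples x feature columns.
#' @param l rank parameter: number of leading right singular vectors,
#'   \code{1 <= l <= min(dim(M))} and at most the numerical rank of \code{M}.
#' @return a [LeverageResult] with empty selection.
#' @export
leverageScores <- function(M, l) {
  M <- as.matrix(M)
  l <- as.integer(l)
  if (l < 1L || l > min(dim(M)))
    stop(sprintf("rank parameter l = %d out of range [1, %d]", l, min(dim(M))))
  sv <- svd(M, nu = 0, nv = min(dim(M)))
  tol <- max(dim(M)) * .Machine$double.eps * sv$d[1]
  numRank <- sum(sv$d > tol)
  if (l > numRank)
    stop(sprintf(
      "l = %d exceeds the numerical rank %d of the matrix; use a smaller l",
      l, numRank))
  V <- sv$v[, seq_len(l), drop = FALSE]
  scores <- rowSums(V^2) / l
  names(scores) <- colnames(M)
  new("LeverageResult", scores = scores, rank = l, selected = integer(0))
}

#' Indices of the k largest scores
#'
#' Ties are broken toward the lowest index; indices are returned in
#' descending-score order.
#'
#' @param scores numeric score vector (or a [LeverageResult]).
#' @param k number of indices to return.
#' @return integer vector of length k.
#' @export
topKIndexes <- function(scores, k) {
  if (is(scores, "LeverageResult")) scores <- leverage(scores)
  k <- as.integer(k)
  if (k < 1L || k > length(scores))
    stop(sprintf("k = %d out of range [1, %d]", k, length(scores)))
  ord <- order(-scores, seq_along(scores))
  ord[seq_len(k)]
}

#' Rank columns by leverage and select the top k
#'
#' @inheritParams leverageScores
#' @param k number of columns to keep.
#' @return a [LeverageResult] with \code{selected} filled.
#' @export
rankColumnsByLeverage <- function(M, l, k) {
  lr <- leverageScores(M, l)
  new("LeverageResult", scores = lr@scores, rank = lr@rank,
      selected = topKIndexes(lr@scores, k))
}

#' Restrict training and test feature matrices to selected columns
#'
#' Applies the same index set in the same order to both matrices, so a
#' position in the reduced representation refers to the same source column
#' (original or synthetic half) in train and test.
#'
#' @param train,test numeric feature matrices with equal column counts.
#' @param idx integer column indices (e.g. from [topKIndexes()]).
#' @return list with reduced \code{train} and \code{test} matrices.
#' @export
selectColumns <- function(train, test, idx) {
  train <- as.matrix(train)
  test <- as.matrix(test)
  if (ncol(train) != ncol(test))
    stop("column-count mismatch: ", ncol(train), " vs ", ncol(test))
  if (length(idx) == 0 || min(idx) < 1 || max(idx) > ncol(train))
    stop("column indices out of range")
  list(train = train[, idx, drop = FALSE],
       test = test[, idx, drop = FALSE])
}
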