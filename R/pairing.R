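## Paired feature construction: each sample is linked with a synthetic
## partner generated by interpolating toward a nearest neighbor, and the two
## profiles are concatenated. Unlike SMOTE, the synthetic profile widens the
## feature vector (2n columns) instead of adding rows.

#' Indices of a row's k' nearest neighbors
#'
#' Euclidean nearest neighbors of \code{M[row, ]} among the other rows of
#' \code{M} (the query row itself is excluded). Distance ties are broken
#' toward the lowest row index, making the search deterministic.
#'
#' @param M numeric matrix, samples x features.
#' @param row query row index.
#' @param kPrime number of neighbors to return.
#' @return integer vector of \code{kPrime} row indices, nearest first.
#' @export
nearestNeighborIndex <- function(M, row, kPrime = 1L) {
  kPrime <- as.integer(kPrime)
  if (kPrime < 1L) stop("kPrime must be a positive integer")
  if (nrow(M) < kPrime + 1L)
    stop(sprintf("need at least kPrime + 1 = %d rows, got %d",
                 kPrime + 1L, nrow(M)))
  d2 <- colSums((t(M) - M[row, ])^2)
  d2[row] <- Inf
  order(d2, seq_along(d2))[seq_len(kPrime)]
}

#' Linear interpolation between two profiles
#'
#' Computes \code{g + (gStar - g) * lambda}, the synthetic profile lying on
#' the segment from \code{g} toward \code{gStar}. \code{lambda = 0} returns
#' \code{g}; \code{lambda = 1} returns \code{gStar}.
#'
#' @param g,gStar numeric vectors of equal length.
#' @param lambda interpolation coefficient.
#' @return numeric vector of the same length.
#' @export
interpolateProfiles <- function(g, gStar, lambda) {
  if (length(g) != length(gStar))
    stop("profiles must have equal length: ", length(g), " vs ", length(gStar))
  g + (gStar - g) * lambda
}

## One synthetic partner per row. With kPrime > 1 the partner is drawn
## uniformly from the kPrime nearest neighbors (caller controls the RNG);
## with kPrime = 1 the construction is fully deterministic.
.syntheticPartners <- function(M, lambda, kPrime) {
  p <- nrow(M)
  synth <- matrix(NA_real_, p, ncol(M))
  for (i in seq_len(p)) {
    nn <- nearestNeighborIndex(M, i, kPrime)
    j <- if (kPrime == 1L) nn[1] else nn[sample.int(kPrime, 1L)]
    synth[i, ] <- interpolateProfiles(M[i, ], M[j, ], lambda)
  }
  synth
}

.buildPaired <- function(M, responses, lambda, kPrime) {
  kPrime <- as.integer(kPrime)
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  .validateExpressionMatrix(M)
  synth <- .syntheticPartners(M, lambda, kPrime)
  feats <- cbind(M, synth)
  colnames(feats) <- c(colnames(M), paste0(colnames(M), ".syn"))
  new("PairedSet", features = feats, responses = responses,
      lambda = lambda, kPrime = kPrime)
}

#' Build the paired training representation
#'
#' For each cell line, finds its nearest neighbor(s) within the training
#' set, interpolates a synthetic profile a fraction \code{lambda} of the way
#' toward the chosen neighbor, concatenates original and synthetic profiles
#' into a 2n-dimensional feature vector, and attaches the cell line's drug
#' response. Row count is preserved.
#'
#' @param D expression matrix, cell lines x genes.
#' @param y drug responses (IC50 scale), named and aligned to \code{D}.
#' @param lambda interpolation coefficient (study value 0.3).
#' @param kPrime neighborhood size (study value 1). For \code{kPrime > 1}
#'   the partner is drawn uniformly among the neighbors; seed the RNG for
#'   reproducibility.
#' @return a [PairedSet] with responses attached.
#' @export
buildPairedTraining <- function(D, y, lambda = 0.3, kPrime = 1L) {
  y <- alignSamples(D, y)
  .buildPaired(D, as.numeric(y), lambda, kPrime)
}

#' Build the paired test representation
#'
#' As [buildPairedTraining()] but over the tumors of the test set: neighbors
#' are searched within the test set itself and no responses are attached.
#'
#' @param T. expression matrix, tumors x genes.
#' @inheritParams buildPairedTraining
#' @return a [PairedSet] without responses.
#' @export
buildPairedTest <- function(T., lambda = 0.3, kPrime = 1L) {
  .buildPaired(T., numeric(0), lambda, kPrime)
}
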