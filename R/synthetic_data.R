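## Seeded synthetic data with the statistical structure the method assumes:
## continuous expression features, a continuous IC50-like response linearly
## driven by a sparse set of informative genes plus Gaussian noise, and test
## tumors drawn from the same generative model whose binary clinical label
## thresholds the same latent response. Continuous features make the
## distance-to-test weights pairwise distinct almost surely, the regime in
## which the filtered-set sizes are fully determined by p and k''.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state, so seeded helpers do not
#' perturb an enclosing simulation.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic cell-line / tumor dataset
#'
#' Training features are i.i.d. standard normal over \code{n} genes for
#' \code{p} cell lines; the response is \code{y = D beta + eps} with
#' \code{beta} nonzero only on \code{nInformative} genes (random signs,
#' magnitudes uniform in \code{[0.5, 1.5] * effectSize}) and
#' \code{eps ~ N(0, noiseSd^2)}. Test tumors are drawn from the same model;
#' a tumor is labeled 1 (resistant) iff its latent response exceeds the
#' \code{labelThreshold} quantile of the realized test latents, so both
#' classes are always present.
#'
#' @param p,q number of training cell lines / test tumors (>= 2).
#' @param n number of genes.
#' @param nInformative number of signal genes (<= n).
#' @param effectSize scale of the nonzero coefficients.
#' @param noiseSd standard deviation of the additive response noise.
#' @param labelThreshold quantile in (0, 1) splitting resistant from
#'   sensitive tumors.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return list with \code{D} (p x n matrix), \code{y} (named responses),
#'   \code{T} (q x n matrix), \code{labels} (named 0/1), and \code{truth}
#'   (informative gene indices, full coefficient vector, latent test
#'   responses).
#' @export
syntheticDataset <- function(p, q, n, nInformative = min(10L, n),
                             effectSize = 1, noiseSd = 1,
                             labelThreshold = 0.5, seed = 1L) {
  p <- as.integer(p); q <- as.integer(q); n <- as.integer(n)
  nInformative <- as.integer(nInformative)
  if (p < 2 || q < 2) stop("p and q must be at least 2")
  if (nInformative < 1 || nInformative > n)
    stop("nInformative must lie in [1, n]")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  if (labelThreshold <= 0 || labelThreshold >= 1)
    stop("labelThreshold must be strictly inside (0, 1)")
  withSeed(seed, {
    genes <- sprintf("G%04d", seq_len(n))
    cells <- sprintf("CL%03d", seq_len(p))
    tumors <- sprintf("TM%03d", seq_len(q))
    D <- matrix(stats::rnorm(p * n), p, n, dimnames = list(cells, genes))
    idx <- sort(sample.int(n, nInformative))
    beta <- numeric(n)
    beta[idx] <- effectSize * sample(c(-1, 1), nInformative, replace = TRUE) *
      stats::runif(nInformative, 0.5, 1.5)
    y <- as.numeric(D %*% beta) + stats::rnorm(p, 0, noiseSd)
    names(y) <- cells
    Tm <- matrix(stats::rnorm(q * n), q, n, dimnames = list(tumors, genes))
    latent <- as.numeric(Tm %*% beta) + stats::rnorm(q, 0, noiseSd)
    labels <- as.integer(latent > stats::quantile(latent, labelThreshold))
    names(labels) <- tumors
    list(D = D, y = y, T = Tm, labels = labels,
         truth = list(informative = idx, beta = beta, latent = latent))
  })
}

#' Deterministic tiny fixtures for unit tests
#'
#' \describe{
#'   \item{"tiny-linear"}{8 training / 4 test samples over 4 genes with
#'     hand-checkable nearest neighbors; the response is exactly twice the
#'     first gene.}
#'   \item{"tied-weights"}{6 training rows containing duplicates, forcing
#'     ties in the distance-to-test weights for partition edge cases.}
#'   \item{"planted-columns"}{a 40 x 100 feature matrix in which a known set
#'     of 20 columns carries a strong low-rank component while the remaining
#'     80 are i.i.d. small noise, for leverage-recovery tests (seeded);
#'     returned as \code{list(M, truth = list(signal = indices))}.}
#' }
#'
#' @param name fixture name.
#' @return list with the same fields as [syntheticDataset()] (fixtures
#'   without a meaningful truth record return \code{truth = NULL}).
#' @export
makeFixture <- function(name) {
  switch(name,
    "tiny-linear" = {
      genes <- paste0("G", 1:4)
      D <- matrix(c(
        0, 0, 0, 0,
        1, 0, 0, 0,
        5, 0, 0, 0,
        0, 3, 0, 0,
        0, 0, 2, 0,
        0, 0, 0, 4,
        2, 2, 0, 0,
        6, 1, 0, 0), nrow = 8, byrow = TRUE,
        dimnames = list(sprintf("CL%03d", 1:8), genes))
      y <- 2 * D[, 1]
      Tm <- matrix(c(
        0.5, 0, 0, 0,
        4, 0, 0, 0,
        0, 2, 1, 0,
        3, 3, 0, 0), nrow = 4, byrow = TRUE,
        dimnames = list(sprintf("TM%03d", 1:4), genes))
      labels <- c(TM001 = 0L, TM002 = 1L, TM003 = 0L, TM004 = 1L)
      list(D = D, y = y, T = Tm, labels = labels, truth = NULL)
    },
    "tied-weights" = {
      genes <- paste0("G", 1:3)
      base <- matrix(c(
        0, 0, 0,
        0, 0, 0,
        1, 1, 1,
        1, 1, 1,
        5, 5, 5,
        9, 9, 9), nrow = 6, byrow = TRUE,
        dimnames = list(sprintf("CL%03d", 1:6), genes))
      y <- c(1, 1, 2, 2, 5, 9)
      names(y) <- rownames(base)
      Tm <- matrix(c(0, 0, 1,
                     2, 2, 2), nrow = 2, byrow = TRUE,
                   dimnames = list(c("TM001", "TM002"), genes))
      labels <- c(TM001 = 0L, TM002 = 1L)
      list(D = base, y = y, T = Tm, labels = labels, truth = NULL)
    },
    "planted-columns" = withSeed(42L, {
      nRow <- 40L; nCol <- 100L; nSignal <- 20L; rnk <- 3L
      signal <- sort(sample.int(nCol, nSignal))
      M <- matrix(stats::rnorm(nRow * nCol, sd = 0.1), nRow, nCol)
      ## strong rank-3 component confined to the signal columns
      U <- matrix(stats::rnorm(nRow * rnk), nRow, rnk)
      V <- matrix(stats::rnorm(nSignal * rnk), nSignal, rnk)
      M[, signal] <- M[, signal] + 3 * tcrossprod(U, V)
      dimnames(M) <- list(sprintf("S%03d", seq_len(nRow)),
                          sprintf("G%04d", seq_len(nCol)))
      list(M = M, truth = list(signal = signal))
    }),
    stop("unknown fixture: ", name)
  )
}
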