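## End-to-end prediction pipelines over raw expression matrices:
##   B  — baseline: fit the learner on the raw training matrix, predict the
##        raw test matrix.
##   A1 — paired representation, link filtering, fit on the filtered set S,
##        predict the paired test set.
##   A2 — A1 plus leverage-score column selection (computed on S, applied
##        identically to S and the paired test set) before the final fit.

.standardizeFit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

.standardizeApply <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, "/")
}

.checkInputs <- function(D, y, T.) {
  .validateExpressionMatrix(D, "training matrix")
  .validateExpressionMatrix(T., "test matrix")
  checkGeneCompatibility(D, T.)
  alignSamples(D, y)
}

#' Baseline drug sensitivity prediction
#'
#' Fits the learner directly on the raw training expression matrix with its
#' IC50 responses and predicts the raw test tumors — the transfer protocol
#' the link-prediction algorithms are compared against.
#'
#' @param D training expression matrix (cell lines x genes).
#' @param y named drug responses aligned to \code{D}.
#' @param T. test expression matrix (tumors x genes, same genes/order as
#'   \code{D}).
#' @param learner final [LearnerSpec].
#' @param standardize z-score columns using training statistics before
#'   fitting and predicting.
#' @return named numeric predictions, one per tumor.
#' @export
runBaseline <- function(D, y, T., learner = learnerSpec("rr"),
                        standardize = FALSE) {
  y <- .checkInputs(D, y, T.)
  Xtr <- D; Xte <- T.
  if (standardize) {
    st <- .standardizeFit(Xtr)
    Xtr <- .standardizeApply(Xtr, st)
    Xte <- .standardizeApply(Xte, st)
  }
  model <- fitLearner(learner, Xtr, as.numeric(y))
  pred <- predict(model, Xte)
  names(pred) <- rownames(T.)
  pred
}

#' Supervised link prediction (paired features + link filtering)
#'
#' Builds the paired representations of training and test sets, filters the
#' training cell lines by distance weighting, median partition, seed
#' assignment and the query-by-committee loop, fits the final learner on the
#' filtered set S, and predicts the paired test tumors.
#'
#' @inheritParams runBaseline
#' @param finalLearner [LearnerSpec] for the final model h.
#' @param lambda interpolation coefficient (study value 0.3).
#' @param kPrime pairing neighborhood size (study value 1).
#' @param kDoubleprime query-by-committee iterations (study value 5).
#' @param committee [CommitteeSpec] scoring disagreement.
#' @param seedLearner [LearnerSpec] for the seed cross-prediction.
#' @param seedRule see [assignSeedSet()].
#' @param seed RNG seed (only consulted when \code{kPrime > 1}, where the
#'   synthetic partner is drawn among several neighbors).
#' @return named numeric predictions with attributes \code{selectedSize}
#'   (rows of S) and \code{featureCount} (columns of the final model).
#' @export
runA1 <- function(D, y, T., finalLearner = learnerSpec("rr"),
                  lambda = 0.3, kPrime = 1L, kDoubleprime = 5L,
                  committee = committeeSpec(),
                  seedLearner = learnerSpec("rr"),
                  seedRule = "as-written", standardize = FALSE,
                  seed = 1L) {
  y <- .checkInputs(D, y, T.)
  pr <- withSeed(seed, {
    G <- buildPairedTraining(D, y, lambda = lambda, kPrime = kPrime)
    Gp <- buildPairedTest(T., lambda = lambda, kPrime = kPrime)
    list(G = G, Gp = Gp)
  })
  S <- linkFilter(pr$G, pr$Gp, committee = committee,
                  seedLearner = seedLearner, kDoubleprime = kDoubleprime,
                  rule = seedRule)
  Xtr <- pairedFeatures(S)
  Xte <- pairedFeatures(pr$Gp)
  if (standardize) {
    st <- .standardizeFit(Xtr)
    Xtr <- .standardizeApply(Xtr, st)
    Xte <- .standardizeApply(Xte, st)
  }
  model <- fitLearner(finalLearner, Xtr, pairedResponses(S))
  pred <- predict(model, Xte)
  names(pred) <- rownames(T.)
  attr(pred, "selectedSize") <- nrow(S)
  attr(pred, "featureCount") <- ncol(Xtr)
  pred
}

#' Extended supervised link prediction (link filtering + leverage selection)
#'
#' As [runA1()], but after link filtering the feature columns of the
#' filtered set S are ranked by CUR normalized statistical leverage scores
#' and only the top \code{topKGenes} columns are kept — the same positions
#' in S and in the paired test set — before the final fit and prediction.
#'
#' @inheritParams runA1
#' @param topKGenes number of feature columns to keep (required; the study
#'   used dataset-specific values).
#' @param curRank rank parameter l for the leverage scores; default
#'   \code{min(dim(S features), 100)} capped at the numerical rank.
#' @return named numeric predictions with attributes \code{selectedSize},
#'   \code{featureCount}, and \code{selectedColumns}.
#' @export
runA2 <- function(D, y, T., finalLearner = learnerSpec("rr"),
                  topKGenes = NULL, curRank = NULL,
                  lambda = 0.3, kPrime = 1L, kDoubleprime = 5L,
                  committee = committeeSpec(),
                  seedLearner = learnerSpec("rr"),
                  seedRule = "as-written", standardize = FALSE,
                  seed = 1L) {
  if (is.null(topKGenes))
    stop("topKGenes is required for the extended algorithm (no silent default)")
  y <- .checkInputs(D, y, T.)
  pr <- withSeed(seed, {
    G <- buildPairedTraining(D, y, lambda = lambda, kPrime = kPrime)
    Gp <- buildPairedTest(T., lambda = lambda, kPrime = kPrime)
    list(G = G, Gp = Gp)
  })
  S <- linkFilter(pr$G, pr$Gp, committee = committee,
                  seedLearner = seedLearner, kDoubleprime = kDoubleprime,
                  rule = seedRule)
  Sfeat <- pairedFeatures(S)
  if (topKGenes > ncol(Sfeat))
    stop("topKGenes exceeds the paired feature count ", ncol(Sfeat))
  l <- if (is.null(curRank)) min(dim(Sfeat), 100L) else as.integer(curRank)
  lr <- rankColumnsByLeverage(Sfeat, l, topKGenes)
  idx <- selectedColumns(lr)
  sel <- selectColumns(Sfeat, pairedFeatures(pr$Gp), idx)
  Xtr <- sel$train
  Xte <- sel$test
  if (standardize) {
    st <- .standardizeFit(Xtr)
    Xtr <- .standardizeApply(Xtr, st)
    Xte <- .standardizeApply(Xte, st)
  }
  model <- fitLearner(finalLearner, Xtr, pairedResponses(S))
  pred <- predict(model, Xte)
  names(pred) <- rownames(T.)
  attr(pred, "selectedSize") <- nrow(S)
  attr(pred, "featureCount") <- ncol(Xtr)
  attr(pred, "selectedColumns") <- idx
  pred
}
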