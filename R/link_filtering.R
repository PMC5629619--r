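## Training-set filtering by relaxed query-by-committee. Cell lines are
## weighted by their minimum Euclidean distance to the test tumors in the
## paired feature space, split at the median weight into a near half X and a
## far half Z, seeded into labeled/unlabeled pools by cross-prediction error,
## and then k'' unlabeled rows with maximal committee disagreement are
## transferred into the labeled pool, which becomes the final training set.

#' Distance-to-test weights for training cell lines
#'
#' Weight of training row i is the minimum Euclidean distance from its
#' paired feature vector to any test tumor's paired feature vector. Small
#' weights mark cell lines that resemble the test cohort (transductive use
#' of unlabeled test geometry; test responses are never touched).
#'
#' @param train training features: a [PairedSet] or numeric matrix (p x 2n).
#' @param test test features: a [PairedSet] or numeric matrix (q x 2n).
#' @return numeric weight vector of length p.
#' @export
computeWeights <- function(train, test) {
  A <- if (is(train, "PairedSet")) pairedFeatures(train) else as.matrix(train)
  B <- if (is(test, "PairedSet")) pairedFeatures(test) else as.matrix(test)
  if (nrow(B) == 0) stop("test set is empty")
  if (ncol(A) != ncol(B))
    stop("feature column mismatch: ", ncol(A), " vs ", ncol(B))
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  w <- sqrt(pmax(apply(d2, 1, min), 0))
  names(w) <- rownames(A)
  w
}

#' Partition a paired training set at the median weight
#'
#' X collects rows with weight at or below the median (near the test set),
#' Z rows at or above it; rows whose weight equals the median appear in
#' both. The median of an even number of weights is the mean of the two
#' middle order statistics, so with distinct weights the two halves are
#' disjoint and of size p/2 (even p) or (p+1)/2 each with a one-row overlap
#' (odd p).
#'
#' @param paired a training [PairedSet].
#' @param w weight vector from [computeWeights()].
#' @return a [LinkPartition].
#' @export
medianPartition <- function(paired, w) {
  if (length(w) != nrow(paired))
    stop("one weight per training row required")
  med <- stats::median(w)
  new("LinkPartition", paired = paired, weights = as.numeric(w), med = med,
      xIdx = which(w <= med), zIdx = which(w >= med))
}

.sideMSE <- function(learner, trainSet, evalSet, sideName) {
  feats <- pairedFeatures(trainSet)
  if (all(apply(feats, 2, function(col) diff(range(col)) == 0)))
    stop("degenerate fit on side ", sideName, ": all feature columns constant")
  model <- tryCatch(
    fitLearner(learner, feats, pairedResponses(trainSet)),
    error = function(e) stop("fit failed on side ", sideName, ": ",
                             conditionMessage(e), call. = FALSE))
  pred <- predict(model, pairedFeatures(evalSet))
  mean((pred - pairedResponses(evalSet))^2)
}

#' Assign seed labeled pool S and unlabeled-role pool U
#'
#' Fits the seed learner on X to predict Z's responses and on Z to predict
#' X's responses, then takes as seed pool S the side whose trained model
#' incurred the LARGER mean squared error (ties favor X, the near-to-test
#' half). The other side becomes the unlabeled-role pool U. Each side's
#' error is the mean squared error over its own prediction set, which
#' coincides with the per-element formulation whenever the two halves have
#' equal size and is the size-robust generalization otherwise.
#'
#' @param part a [LinkPartition].
#' @param seedLearner learner used for the cross-prediction (study choice:
#'   ridge regression).
#' @param rule \code{"as-written"} keeps the larger-error side as S;
#'   \code{"inverted"} swaps the roles (the smaller-error side becomes S).
#' @return a [SeedAssignment].
#' @export
assignSeedSet <- function(part, seedLearner = learnerSpec("rr"),
                          rule = c("as-written", "inverted")) {
  rule <- match.arg(rule)
  if (!length(part@xIdx) || !length(part@zIdx))
    stop("both partition halves must be non-empty")
  X <- partitionX(part)
  Z <- partitionZ(part)
  mseXonZ <- .sideMSE(seedLearner, X, Z, "X")
  mseZonX <- .sideMSE(seedLearner, Z, X, "Z")
  jStar <- which.max(c(mseXonZ, mseZonX))  # ties -> 1 (S = X)
  if (rule == "inverted") jStar <- 3L - jStar
  sIdx <- if (jStar == 1L) part@xIdx else part@zIdx
  uIdx <- if (jStar == 1L) part@zIdx else part@xIdx
  new("SeedAssignment", paired = part@paired, sIdx = sIdx, uIdx = uIdx,
      jStar = as.integer(jStar), perSideMSE = c(mseXonZ, mseZonX))
}

#' Default committee: three equally weighted SVRs
#'
#' Linear, degree-5 polynomial, and sigmoid kernel support vector
#' regressions with weights 1/3 each, as used in the study.
#'
#' @param members list of [LearnerSpec] objects.
#' @param weights member weights, summing to 1.
#' @return a [CommitteeSpec].
#' @export
committeeSpec <- function(members = list(learnerSpec("svr-linear"),
                                         learnerSpec("svr-poly5"),
                                         learnerSpec("svr-sigmoid")),
                          weights = rep(1 / length(members), length(members))) {
  new("CommitteeSpec", members = members, weights = weights)
}

#' Committee disagreement scores
#'
#' For each column j of the member-by-instance prediction matrix, computes
#' the weighted ensemble average f'_j = sum_i w'_i pred_ij and the weighted
#' squared deviation sum_i w'_i (pred_ij - f'_j)^2 — a weighted prediction
#' variance. Instances where all members agree score 0.
#'
#' @param memberPredictions t x m numeric matrix: one row per committee
#'   member, one column per scored instance.
#' @param wPrime member weights; must sum to 1 (tolerance 1e-9).
#' @return numeric vector of m disagreement scores.
#' @export
disagreementScores <- function(memberPredictions, wPrime) {
  memberPredictions <- as.matrix(memberPredictions)
  if (length(wPrime) != nrow(memberPredictions))
    stop("one weight per committee member required")
  if (abs(sum(wPrime) - 1) > 1e-9)
    stop("committee weights must sum to 1, got ", sum(wPrime))
  fbar <- colSums(wPrime * memberPredictions)
  colSums(wPrime * sweep(memberPredictions, 2, fbar)^2)
}

#' Relaxed query-by-committee training-set selection
#'
#' Starting from the seed assignment, repeats \code{kDoubleprime} times: fit
#' every committee member on the current labeled pool S, score every row of
#' the unlabeled-role pool U by committee disagreement, and transfer the
#' highest-scoring row (ties toward the lowest index) together with its
#' stored drug response from U to S. The returned S is the filtered
#' training set; its size is |S_seed| + k''.
#'
#' @param seed a [SeedAssignment].
#' @param committee a [CommitteeSpec]; default three equally weighted SVRs.
#' @param kDoubleprime number of transfer iterations (study value 5).
#' @return the selected training [PairedSet].
#' @export
qbcSelect <- function(seed, committee = committeeSpec(), kDoubleprime = 5L) {
  kDoubleprime <- as.integer(kDoubleprime)
  if (kDoubleprime < 0L) stop("kDoubleprime must be nonnegative")
  if (kDoubleprime > length(seed@uIdx))
    stop(sprintf("kDoubleprime = %d exceeds unlabeled pool size %d",
                 kDoubleprime, length(seed@uIdx)))
  sIdx <- seed@sIdx
  uIdx <- seed@uIdx
  paired <- seed@paired
  feats <- pairedFeatures(paired)
  resp <- pairedResponses(paired)
  for (iter in seq_len(kDoubleprime)) {
    preds <- vapply(committee@members, function(spec) {
      model <- fitLearner(spec, feats[sIdx, , drop = FALSE], resp[sIdx])
      predict(model, feats[uIdx, , drop = FALSE])
    }, numeric(length(uIdx)))
    preds <- matrix(preds, nrow = length(uIdx))  # guard the single-row case
    scores <- disagreementScores(t(preds), committee@weights)
    pick <- which.max(scores)  # first max -> lowest index
    sIdx <- c(sIdx, uIdx[pick])
    uIdx <- uIdx[-pick]
  }
  paired[sort(sIdx)]
}

#' Full link-filtering chain
#'
#' Convenience wrapper running weighting, median partition, seed assignment,
#' and the query-by-committee loop, returning the filtered training set.
#'
#' @param pairedTrain training [PairedSet] (responses attached).
#' @param pairedTest test [PairedSet].
#' @inheritParams qbcSelect
#' @inheritParams assignSeedSet
#' @return the selected training [PairedSet].
#' @export
linkFilter <- function(pairedTrain, pairedTest, committee = committeeSpec(),
                       seedLearner = learnerSpec("rr"), kDoubleprime = 5L,
                       rule = c("as-written", "inverted")) {
  w <- computeWeights(pairedTrain, pairedTest)
  part <- medianPartition(pairedTrain, w)
  seed <- assignSeedSet(part, seedLearner, rule = rule)
  qbcSelect(seed, committee, kDoubleprime)
}
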