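#' @import methods
NULL

#' Paired (original, synthetic) feature representation
#'
#' A \code{PairedSet} holds the link-prediction feature representation of an
#' expression data set: each sample's profile over \code{n} genes is
#' concatenated with a synthetic profile interpolated toward one of its
#' nearest neighbors, giving \code{2n} feature columns. Training sets carry
#' the drug response (IC50) of the original sample; test sets do not.
#'
#' @slot features numeric matrix, samples x (2n) paired feature columns;
#'   rownames are sample identifiers.
#' @slot responses numeric vector of drug responses, one per row for a
#'   training set, or length zero for a test set.
#' @slot lambda interpolation coefficient used to build the synthetic halves.
#' @slot kPrime number of nearest neighbors considered per sample.
#'
#' @seealso [buildPairedTraining()], [buildPairedTest()]
#' @export
setClass("PairedSet",
  representation(
    features = "matrix",
    responses = "numeric",
    lambda = "numeric",
    kPrime = "integer"
  )
)

setValidity("PairedSet", function(object) {
  msg <- character(0)
  if (!is.numeric(object@features))
    msg <- c(msg, "features must be a numeric matrix")
  if (ncol(object@features) %% 2L != 0L)
    msg <- c(msg, "features must have an even number of columns (2n)")
  if (is.null(rownames(object@features)))
    msg <- c(msg, "features must have sample identifiers as rownames")
  if (!length(object@responses) %in% c(0L, nrow(object@features)))
    msg <- c(msg, "responses must be empty (test set) or one per sample")
  if (any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite")
  if (length(msg)) msg else TRUE
})

#' Median partition of a paired training set
#'
#' Result of splitting a paired training set at the median of the
#' minimum-distance-to-test weights: \code{X} collects the samples at or
#' below the median weight (near the test set), \code{Z} those at or above
#' it. Samples whose weight equals the median belong to both halves.
#'
#' @slot paired the [PairedSet] that was partitioned.
#' @slot weights per-sample minimum Euclidean distance to the test set.
#' @slot med median of \code{weights}.
#' @slot xIdx,zIdx integer row indices of the X (near) and Z (far) halves.
#' @export
setClass("LinkPartition",
  representation(
    paired = "PairedSet",
    weights = "numeric",
    med = "numeric",
    xIdx = "integer",
    zIdx = "integer"
  )
)

setValidity("LinkPartition", function(object) {
  p <- nrow(object@paired@features)
  if (length(object@weights) != p)
    return("weights must have one entry per paired-set row")
  if (!all(sort(union(object@xIdx, object@zIdx)) == seq_len(p)))
    return("X and Z must jointly cover all rows")
  TRUE
})

#' Seed assignment of labeled (S) and unlabeled-role (U) pools
#'
#' Cross-prediction outcome of the relaxed query-by-committee setup: a seed
#' learner trained on each half of a [LinkPartition] predicts the other
#' half's responses, and the half whose model incurred the larger mean
#' squared error becomes the initial labeled pool S; the other half plays
#' the unlabeled-role pool U (its known responses are only looked up when a
#' row is transferred).
#'
#' @slot paired the underlying [PairedSet].
#' @slot sIdx,uIdx row indices of S and U.
#' @slot jStar 1 if the X-trained side had the larger error (S = X), else 2.
#' @slot perSideMSE mean squared errors: X-trained-on-Z, Z-trained-on-X.
#' @export
setClass("SeedAssignment",
  representation(
    paired = "PairedSet",
    sIdx = "integer",
    uIdx = "integer",
    jStar = "integer",
    perSideMSE = "numeric"
  )
)

#' Regression learner specification
#'
#' @slot family one of \code{"rr"} (ridge regression), \code{"svr-linear"},
#'   \code{"svr-sigmoid"}, \code{"svr-poly5"}.
#' @slot params named list of hyperparameters (ridge: \code{alpha}; SVR:
#'   \code{cost}, \code{epsilon}, \code{gamma}, \code{coef0}, \code{degree}).
#' @export
setClass("LearnerSpec",
  representation(family = "character", params = "list")
)

setValidity("LearnerSpec", function(object) {
  fams <- c("rr", "svr-linear", "svr-sigmoid", "svr-poly5")
  if (!object@family %in% fams)
    return(sprintf("unknown learner family '%s' (expected one of %s)",
                   object@family, paste(fams, collapse = ", ")))
  p <- object@params
  if (object@family == "rr" && p$alpha <= 0)
    return("ridge penalty alpha must be > 0")
  if (object@family != "rr") {
    if (p$cost <= 0) return("SVR cost must be > 0")
    if (p$epsilon < 0) return("SVR epsilon must be >= 0")
    if (object@family == "svr-poly5" && p$degree != 5L)
      return("svr-poly5 uses a fixed polynomial degree of 5")
  }
  TRUE
})

#' Fitted regression model
#'
#' @slot spec the [LearnerSpec] used.
#' @slot fit opaque learned state (ridge coefficients or an e1071 svm fit).
#' @slot nFeatures number of feature columns the model accepts.
#' @slot constant for degenerate constant-target fits, the constant predicted
#'   value (length zero otherwise).
#' @export
setClass("FittedModel",
  representation(
    spec = "LearnerSpec",
    fit = "ANY",
    nFeatures = "integer",
    constant = "numeric"
  )
)

#' Committee of regression learners
#'
#' The committee scoring disagreement in the query-by-committee loop. The
#' default follows the study design: three support vector regressions with
#' linear, degree-5 polynomial, and sigmoid kernels, equally weighted.
#'
#' @slot members list of [LearnerSpec] objects.
#' @slot weights nonnegative member weights summing to 1.
#' @export
setClass("CommitteeSpec",
  representation(members = "list", weights = "numeric")
)

setValidity("CommitteeSpec", function(object) {
  if (length(object@members) != length(object@weights))
    return("one weight per committee member required")
  if (!all(vapply(object@members, is, logical(1), class2 = "LearnerSpec")))
    return("members must be LearnerSpec objects")
  if (any(object@weights < 0))
    return("committee weights must be nonnegative")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("committee weights must sum to 1")
  TRUE
})

#' CUR statistical leverage scores over feature columns
#'
#' @slot scores normalized statistical leverage score per column; nonnegative
#'   and summing to 1.
#' @slot rank rank parameter l (number of top right singular vectors used).
#' @slot selected integer indices of selected columns, in descending-score
#'   order (may be empty if no selection was made).
#' @export
setClass("LeverageResult",
  representation(scores = "numeric", rank = "integer", selected = "integer")
)

setValidity("LeverageResult", function(object) {
  if (any(object@scores < -1e-12))
    return("leverage scores must be nonnegative")
  if (abs(sum(object@scores) - 1) > 1e-9)
    return("leverage scores must sum to 1")
  if (anyDuplicated(object@selected))
    return("selected indices must be unique")
  if (length(object@selected) &&
      (min(object@selected) < 1 || max(object@selected) > length(object@scores)))
    return("selected indices out of range")
  TRUE
})

#' Evaluation report over algorithms and training-size reduction runs
#'
#' @slot perRun data.frame with columns \code{algorithm}, \code{learner},
#'   \code{run}, \code{size}, \code{auc}.
#' @slot mauc named numeric, mean AUC per algorithm/learner combination.
#' @slot pairwiseWilcoxon matrix of two-tailed Wilcoxon signed-rank p-values
#'   over combination pairs (NA diagonal), or a 0x0 matrix.
#' @slot groupTTest named numeric of two-tailed t-test p-values comparing
#'   predicted scores between clinical groups at full training size (may be
#'   empty when no labels were supplied).
#' @export
setClass("EvalReport",
  representation(
    perRun = "data.frame",
    mauc = "numeric",
    pairwiseWilcoxon = "matrix",
    groupTTest = "numeric"
  )
)
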