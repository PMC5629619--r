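## Uniform fit/predict contract over the regression algorithms used in the
## study: ridge regression (seed learner and final learner) and epsilon-SVR
## with linear, sigmoid, and degree-5 polynomial kernels (committee members
## and final learners). SVR is backed by libsvm via e1071; ridge is solved in
## closed form with an unpenalized intercept.

#' Construct a learner specification
#'
#' @param family \code{"rr"} (ridge regression), \code{"svr-linear"},
#'   \code{"svr-sigmoid"}, or \code{"svr-poly5"}.
#' @param alpha ridge penalty on coefficients (intercept unpenalized).
#' @param cost SVR cost C.
#' @param epsilon SVR tube width.
#' @param gamma SVR kernel coefficient; \code{NULL} means the libsvm default
#'   1 / (number of feature columns), resolved at fit time.
#' @param coef0 offset of the sigmoid/polynomial kernels.
#' @return a [LearnerSpec].
#' @export
learnerSpec <- function(family = c("rr", "svr-linear", "svr-sigmoid", "svr-poly5"),
                        alpha = 1, cost = 1, epsilon = 0.1,
                        gamma = NULL, coef0 = 0) {
  family <- match.arg(family)
  params <- if (family == "rr") list(alpha = alpha)
  else list(cost = cost, epsilon = epsilon, gamma = gamma, coef0 = coef0,
            degree = if (family == "svr-poly5") 5L else 3L)
  new("LearnerSpec", family = family, params = params)
}

#' Parse a learner specification string
#'
#' Accepts \code{"family"} or \code{"family:key=value,key=value"} as used on
#' the command line, e.g. \code{"rr:alpha=0.5"} or
#' \code{"svr-linear:cost=2,epsilon=0.05"}.
#'
#' @param s specification string.
#' @return a [LearnerSpec].
#' @export
parseLearnerSpec <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  family <- parts[1]
  if (!family %in% c("rr", "svr-linear", "svr-sigmoid", "svr-poly5"))
    stop("unknown learner family: ", family)
  args <- list(family = family)
  if (length(parts) > 1) {
    for (kv in strsplit(parts[2], ",", fixed = TRUE)[[1]]) {
      kvp <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(kvp) != 2) stop("malformed learner option: ", kv)
      args[[kvp[1]]] <- as.numeric(kvp[2])
    }
  }
  do.call(learnerSpec, args)
}

## Ridge with unpenalized intercept: center features and response, penalize
## coefficients only. Uses the dual form when features outnumber samples
## (paired representations have 2n >> p in realistic settings).
.ridgeFit <- function(X, y, alpha) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  if (ncol(Xc) <= nrow(Xc)) {
    A <- crossprod(Xc)
    diag(A) <- diag(A) + alpha
    beta <- solve(A, crossprod(Xc, yc))
  } else {
    K <- tcrossprod(Xc)
    diag(K) <- diag(K) + alpha
    beta <- crossprod(Xc, solve(K, yc))
  }
  list(beta = as.numeric(beta), intercept = ym - sum(xm * beta))
}

.svmKernel <- c("svr-linear" = "linear", "svr-sigmoid" = "sigmoid",
                "svr-poly5" = "polynomial")

#' Fit a regression learner
#'
#' Deterministic for fixed input and specification. Constant targets yield a
#' degenerate model that predicts the constant for any input (libsvm would
#' otherwise return an empty model with no support vectors).
#'
#' @param spec a [LearnerSpec].
#' @param X numeric feature matrix (samples x features).
#' @param y numeric target vector.
#' @return a [FittedModel].
#' @export
fitLearner <- function(spec, X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training rows, got ", nrow(X))
  if (length(y) != nrow(X)) stop("targets must match rows: ",
                                 length(y), " vs ", nrow(X))
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in training data")
  if (diff(range(y)) == 0)
    return(new("FittedModel", spec = spec, fit = NULL,
               nFeatures = ncol(X), constant = y[1]))
  fit <- if (spec@family == "rr") {
    .ridgeFit(X, y, spec@params$alpha)
  } else {
    p <- spec@params
    gamma <- if (is.null(p$gamma)) 1 / ncol(X) else p$gamma
    e1071::svm(x = X, y = y, type = "eps-regression", scale = FALSE,
               kernel = .svmKernel[[spec@family]], degree = p$degree,
               gamma = gamma, coef0 = p$coef0, cost = p$cost,
               epsilon = p$epsilon, fitted = FALSE)
  }
  new("FittedModel", spec = spec, fit = fit, nFeatures = ncol(X),
      constant = numeric(0))
}

#' Predict drug responses from a fitted model
#'
#' @param object a [FittedModel].
#' @param newdata numeric matrix with the same number of feature columns the
#'   model was fitted on. Zero rows yield an empty vector.
#' @param ... ignored.
#' @return numeric vector, one prediction per row of \code{newdata}.
#' @export
setMethod("predict", "FittedModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object@nFeatures)
    stop(sprintf("feature count mismatch: model expects %d, got %d",
                 object@nFeatures, ncol(newdata)))
  if (nrow(newdata) == 0) return(numeric(0))
  if (length(object@constant))
    return(rep(object@constant, nrow(newdata)))
  if (object@spec@family == "rr") {
    as.numeric(newdata %*% object@fit$beta + object@fit$intercept)
  } else if (object@fit$tot.nSV == 0) {
    ## inside-the-tube degenerate libsvm solution: decision value is -rho
    rep(-object@fit$rho, nrow(newdata))
  } else {
    as.numeric(stats::predict(object@fit, newdata))
  }
})
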