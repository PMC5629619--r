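## Evaluation protocol: AUC of the continuous predicted responses against
## binary clinical outcomes, mean AUC (MAUC) over a decreasing-training-size
## schedule of runs, two-tailed Wilcoxon signed-rank tests between paired
## per-run AUCs of algorithms, and two-sample t-tests between the predicted
## scores of clinical groups.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a uniformly chosen positive sample receives a higher
#' score than a uniformly chosen negative one, with half credit for ties.
#' Predictions are on the IC50 scale, so the resistant class (label 1) is
#' expected to score higher.
#'
#' @param scores numeric predicted scores.
#' @param labels binary labels, same length as \code{scores}.
#' @param positiveClass label value treated as positive (default 1,
#'   resistant / non-responder).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels, positiveClass = 1L) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  pos <- labels == positiveClass
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)  # midranks for ties
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Mean AUC over runs
#'
#' @param aucs numeric vector of per-run AUC values.
#' @return arithmetic mean.
#' @export
mauc <- function(aucs) {
  if (length(aucs) == 0) stop("no AUC values supplied")
  mean(aucs)
}

#' Nested training-subset schedule of decreasing sizes
#'
#' Produces one index subset per requested size. The first size must equal
#' the full training size and sizes must be strictly decreasing; each run's
#' subset is obtained from the previous one by removing samples uniformly at
#' random, so later runs are nested within earlier ones. The removal is
#' driven by \code{seed} only and leaves the caller's RNG state untouched.
#'
#' @param p full training size (or an object with rows, e.g. the training
#'   matrix).
#' @param sizes strictly decreasing integer sizes, first equal to \code{p}.
#' @param seed integer seed for the removal draws.
#' @return list of integer index vectors, one per size.
#' @export
reductionRuns <- function(p, sizes, seed = 1L) {
  if (!is.numeric(p) || length(p) != 1) p <- nrow(p)
  sizes <- as.integer(sizes)
  if (any(diff(sizes) >= 0)) stop("sizes must be strictly decreasing")
  if (sizes[1] != p)
    stop("first size must equal the full training size ", p)
  if (sizes[length(sizes)] < 1) stop("sizes must be positive")
  runs <- vector("list", length(sizes))
  runs[[1]] <- seq_len(p)
  withSeed(seed, {
    for (i in seq_along(sizes)[-1]) {
      prev <- runs[[i - 1]]
      drop <- sample(prev, length(prev) - sizes[i])
      runs[[i]] <- sort(setdiff(prev, drop))
    }
  })
  runs
}

#' Two-tailed Wilcoxon signed-rank test
#'
#' Paired test on \code{a - b}. Zero differences are dropped; absolute
#' differences are ranked with midranks for ties. The default mode is the
#' normal approximation WITHOUT continuity correction and with the plain
#' variance n(n+1)(2n+1)/24; a continuity-corrected and an exact enumeration
#' mode are available, and \code{tieCorrect = TRUE} subtracts the usual
#' midrank tie adjustment from the variance. If every difference is zero the
#' test is degenerate and p = 1 is returned with a flag.
#'
#' @param a,b paired numeric vectors of equal length (>= 2).
#' @param mode \code{"normal"} (default), \code{"continuity"}, or
#'   \code{"exact"} (full sign-pattern enumeration; n of nonzero differences
#'   at most 20).
#' @param tieCorrect apply the tie adjustment sum(t^3 - t)/48 to the normal
#'   variance (off by default).
#' @return list with \code{statistic} (positive-rank sum W), \code{p.value},
#'   \code{nUsed} (nonzero differences), and \code{degenerate}.
#' @export
wilcoxonSignedRank <- function(a, b, mode = c("normal", "continuity", "exact"),
                               tieCorrect = FALSE) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p.value = 1, nUsed = 0L,
                degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (mode == "exact") {
    if (n > 20) stop("exact enumeration limited to 20 nonzero differences")
    ## distribution of W over all 2^n equiprobable sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.numeric(signs %*% r)
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-12)
  } else {
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24
    if (tieCorrect) {
      ties <- table(r)
      sigma2 <- sigma2 - sum(ties^3 - ties) / 48
    }
    z <- W - mu
    if (mode == "continuity") z <- z - sign(z) * 0.5
    p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  }
  list(statistic = W, p.value = min(p, 1), nUsed = n, degenerate = FALSE)
}

#' Two-sample t-test between predicted scores of clinical groups
#'
#' Compares the predicted responses of the two label groups (e.g. sensitive
#' vs resistant); Welch's unequal-variance test by default.
#'
#' @param predictions numeric predicted responses.
#' @param labels binary group labels.
#' @param varEqual use the pooled-variance Student test instead of Welch.
#' @return two-tailed p-value.
#' @export
groupTTest <- function(predictions, labels, varEqual = FALSE) {
  g0 <- predictions[labels == 0]
  g1 <- predictions[labels == 1]
  if (length(g0) < 2 || length(g1) < 2)
    stop("both groups need at least 2 members")
  if (stats::sd(g0) == 0 && stats::sd(g1) == 0) {
    # both groups constant: identical means are indistinguishable (p = 1),
    # different means are separated with certainty
    return(if (mean(g0) == mean(g1)) 1 else 0)
  }
  stats::t.test(g1, g0, var.equal = varEqual)$p.value
}

#' Benchmark algorithms over a training-size reduction schedule
#'
#' Runs every algorithm x learner combination on every nested training
#' subset of the schedule, scores each run's test predictions by AUC against
#' the clinical labels, and summarizes: per-run AUC table, MAUC per
#' combination, pairwise two-tailed Wilcoxon signed-rank p-values between
#' combinations over their paired per-run AUCs, and a group t-test on the
#' full-size run of each combination.
#'
#' @param D training expression matrix (cell lines x genes).
#' @param y named drug response vector aligned to \code{D}.
#' @param T. test expression matrix (tumors x genes).
#' @param labels named binary clinical labels over the tumors.
#' @param algorithms subset of \code{c("B", "A1", "A2")}.
#' @param learners list of [LearnerSpec] (or spec strings); default ridge
#'   plus linear- and sigmoid-kernel SVR, the study's nine-combination grid
#'   when crossed with the three algorithms.
#' @param sizes reduction schedule (first = full size); default the full
#'   size only.
#' @param seed seed for subset removal and any pairing randomness.
#' @param topKGenes number of columns kept by A2 (required when A2 is run).
#' @param positiveClass label treated as positive for AUC.
#' @param ... further arguments passed to [runA1()] / [runA2()]
#'   (\code{lambda}, \code{kPrime}, \code{kDoubleprime}, \code{committee},
#'   \code{seedLearner}, \code{curRank}, \code{standardize}).
#' @return an [EvalReport].
#' @export
runBenchmark <- function(D, y, T., labels,
                         algorithms = c("B", "A1", "A2"),
                         learners = list(learnerSpec("svr-linear"),
                                         learnerSpec("svr-sigmoid"),
                                         learnerSpec("rr")),
                         sizes = nrow(D), seed = 1L, topKGenes = NULL,
                         positiveClass = 1L, ...) {
  algorithms <- match.arg(algorithms, c("B", "A1", "A2"), several.ok = TRUE)
  learners <- lapply(learners, function(s)
    if (is.character(s)) parseLearnerSpec(s) else s)
  y <- alignSamples(D, y)
  labels <- alignSamples(T., labels)
  runs <- reductionRuns(nrow(D), sizes, seed)
  dots <- list(...)
  rows <- list()
  fullPreds <- list()
  for (alg in algorithms) {
    for (ln in learners) {
      combo <- paste0(alg, "+", ln@family)
      for (r in seq_along(runs)) {
        idx <- runs[[r]]
        Dr <- D[idx, , drop = FALSE]
        yr <- y[idx]
        pred <- switch(alg,
          B = runBaseline(Dr, yr, T., learner = ln),
          A1 = do.call(runA1, c(list(Dr, yr, T., finalLearner = ln,
                                     seed = seed), dots)),
          A2 = do.call(runA2, c(list(Dr, yr, T., finalLearner = ln,
                                     topKGenes = topKGenes, seed = seed),
                                dots)))
        rows[[length(rows) + 1]] <- data.frame(
          algorithm = alg, learner = ln@family, run = r,
          size = length(idx),
          auc = aucScore(pred, labels, positiveClass),
          stringsAsFactors = FALSE)
        if (r == 1) fullPreds[[combo]] <- as.numeric(pred)
      }
    }
  }
  perRun <- do.call(rbind, rows)
  combos <- unique(paste0(perRun$algorithm, "+", perRun$learner))
  maucs <- vapply(combos, function(cb) {
    sel <- paste0(perRun$algorithm, "+", perRun$learner) == cb
    mauc(perRun$auc[sel])
  }, numeric(1))
  wil <- matrix(NA_real_, length(combos), length(combos),
                dimnames = list(combos, combos))
  if (length(runs) >= 2) {
    aucVec <- function(cb) {
      sel <- paste0(perRun$algorithm, "+", perRun$learner) == cb
      perRun$auc[sel][order(perRun$run[sel])]
    }
    for (i in seq_along(combos))
      for (j in seq_along(combos))
        if (i != j)
          wil[i, j] <- wilcoxonSignedRank(aucVec(combos[i]),
                                          aucVec(combos[j]))$p.value
  }
  tt <- vapply(combos, function(cb)
    tryCatch(groupTTest(fullPreds[[cb]], labels == positiveClass),
             error = function(e) NA_real_), numeric(1))
  new("EvalReport", perRun = perRun, mauc = maucs, pairwiseWilcoxon = wil,
      groupTTest = tt)
}

#' Write an evaluation report as JSON
#'
#' @param report an [EvalReport].
#' @param path output path.
#' @export
writeEvalReport <- function(report, path) {
  out <- list(
    per_run = report@perRun,
    mauc = as.list(report@mauc),
    pairwise_wilcoxon = report@pairwiseWilcoxon,
    group_ttest_p = as.list(report@groupTTest)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
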