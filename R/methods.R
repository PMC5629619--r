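#' @describeIn PairedSet-class the samples x 2n paired feature matrix
#' @export
setMethod("pairedFeatures", "PairedSet", function(x) x@features)

#' @describeIn PairedSet-class the response vector (length zero for test sets)
#' @export
setMethod("pairedResponses", "PairedSet", function(x) x@responses)

#' @describeIn PairedSet-class whether responses are attached (training set)
#' @export
setMethod("hasResponses", "PairedSet", function(x) length(x@responses) > 0L)

#' @describeIn PairedSet-class sample identifiers
#' @export
setMethod("sampleIds", "PairedSet", function(x) rownames(x@features))

#' @describeIn PairedSet-class dimensions of the feature matrix
#' @export
setMethod("dim", "PairedSet", function(x) dim(x@features))

#' @describeIn PairedSet-class row subsetting, keeping responses aligned
#' @param i integer or logical row index
#' @param j,drop,... ignored (column structure is fixed at 2n)
#' @export
setMethod("[", "PairedSet", function(x, i, j, ..., drop = FALSE) {
  feats <- x@features[i, , drop = FALSE]
  resp <- if (hasResponses(x)) x@responses[i] else numeric(0)
  new("PairedSet", features = feats, responses = resp,
      lambda = x@lambda, kPrime = x@kPrime)
})

setMethod("show", "PairedSet", function(object) {
  cat(sprintf("PairedSet: %d samples x %d paired features (n = %d genes)\n",
              nrow(object@features), ncol(object@features),
              ncol(object@features) %/% 2L))
  cat(sprintf("  %s | lambda = %g, k' = %d\n",
              if (hasResponses(object)) "training (responses attached)"
              else "test (no responses)",
              object@lambda, object@kPrime))
})

#' @describeIn LinkPartition-class the near-to-test half X as a PairedSet
#' @export
setMethod("partitionX", "LinkPartition", function(x) x@paired[x@xIdx])

#' @describeIn LinkPartition-class the far-from-test half Z as a PairedSet
#' @export
setMethod("partitionZ", "LinkPartition", function(x) x@paired[x@zIdx])

#' @describeIn LinkPartition-class the median weight used as threshold
#' @export
setMethod("partitionMedian", "LinkPartition", function(x) x@med)

setMethod("show", "LinkPartition", function(object) {
  cat(sprintf("LinkPartition: |X| = %d, |Z| = %d (median weight %.4g)\n",
              length(object@xIdx), length(object@zIdx), object@med))
})

#' @describeIn SeedAssignment-class the initial labeled pool S
#' @export
setMethod("seedSet", "SeedAssignment", function(x) x@paired[x@sIdx])

#' @describeIn SeedAssignment-class the unlabeled-role pool U
#' @export
setMethod("unlabeledPool", "SeedAssignment", function(x) x@paired[x@uIdx])

setMethod("show", "SeedAssignment", function(object) {
  side <- if (object@jStar == 1L) "X" else "Z"
  cat(sprintf(
    "SeedAssignment: S = %s (|S| = %d, |U| = %d); cross-prediction MSE %.4g / %.4g\n",
    side, length(object@sIdx), length(object@uIdx),
    object@perSideMSE[1], object@perSideMSE[2]))
})

setMethod("show", "LearnerSpec", function(object) {
  ps <- paste(names(object@params),
              vapply(object@params, format, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("LearnerSpec: %s (%s)\n", object@family, ps))
})

setMethod("show", "CommitteeSpec", function(object) {
  cat(sprintf("CommitteeSpec: %d members (%s), weights %s\n",
              length(object@members),
              paste(vapply(object@members, function(m) m@family,
                           character(1)), collapse = ", "),
              paste(format(object@weights, digits = 3), collapse = ", ")))
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel: %s on %d features%s\n", object@spec@family,
              object@nFeatures,
              if (length(object@constant)) " (degenerate constant fit)" else ""))
})

#' @describeIn LeverageResult-class the normalized leverage score vector
#' @export
setMethod("leverage", "LeverageResult", function(x) x@scores)

#' @describeIn LeverageResult-class selected column indices (descending score)
#' @export
setMethod("selectedColumns", "LeverageResult", function(x) x@selected)

setMethod("show", "LeverageResult", function(object) {
  cat(sprintf("LeverageResult: %d columns, rank l = %d, %d selected\n",
              length(object@scores), object@rank, length(object@selected)))
})

#' @describeIn EvalReport-class per-run AUC table
#' @export
setMethod("perRunAUC", "EvalReport", function(x) x@perRun)

#' @describeIn EvalReport-class mean AUC per algorithm/learner combination
#' @export
setMethod("maucValues", "EvalReport", function(x) x@mauc)

#' @describeIn EvalReport-class pairwise Wilcoxon signed-rank p-value matrix
#' @export
setMethod("pairwiseWilcoxon", "EvalReport", function(x) x@pairwiseWilcoxon)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d runs x %d algorithm combinations\n",
              length(unique(object@perRun$run)),
              length(object@mauc)))
  if (length(object@mauc)) {
    cat("  MAUC:\n")
    m <- sort(object@mauc, decreasing = TRUE)
    for (nm in names(m)) cat(sprintf("    %-16s %.3f\n", nm, m[[nm]]))
  }
})
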