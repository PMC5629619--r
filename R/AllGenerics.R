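#' @rdname PairedSet-class
#' @param x,object a \code{PairedSet}
#' @export
setGeneric("pairedFeatures", function(x) standardGeneric("pairedFeatures"))

#' @rdname PairedSet-class
#' @export
setGeneric("pairedResponses", function(x) standardGeneric("pairedResponses"))

#' @rdname PairedSet-class
#' @export
setGeneric("hasResponses", function(x) standardGeneric("hasResponses"))

#' @rdname PairedSet-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname LinkPartition-class
#' @param x a \code{LinkPartition}
#' @export
setGeneric("partitionX", function(x) standardGeneric("partitionX"))

#' @rdname LinkPartition-class
#' @export
setGeneric("partitionZ", function(x) standardGeneric("partitionZ"))

#' @rdname LinkPartition-class
#' @export
setGeneric("partitionMedian", function(x) standardGeneric("partitionMedian"))

#' @rdname SeedAssignment-class
#' @param x a \code{SeedAssignment}
#' @export
setGeneric("seedSet", function(x) standardGeneric("seedSet"))

#' @rdname SeedAssignment-class
#' @export
setGeneric("unlabeledPool", function(x) standardGeneric("unlabeledPool"))

#' @rdname LeverageResult-class
#' @param x a \code{LeverageResult}
#' @export
setGeneric("leverage", function(x) standardGeneric("leverage"))

#' @rdname LeverageResult-class
#' @export
setGeneric("selectedColumns", function(x) standardGeneric("selectedColumns"))

#' @rdname EvalReport-class
#' @param x an \code{EvalReport}
#' @export
setGeneric("perRunAUC", function(x) standardGeneric("perRunAUC"))

#' @rdname EvalReport-class
#' @export
setGeneric("maucValues", function(x) standardGeneric("maucValues"))

#' @rdname EvalReport-class
#' @export
setGeneric("pairwiseWilcoxon", function(x) standardGeneric("pairwiseWilcoxon"))
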