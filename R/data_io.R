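## Expression matrices are plain numeric matrices: rows = samples, columns =
## genes, dimnames carry the identifiers. Response vectors and clinical labels
## are named numeric/integer vectors. These readers enforce the alignment and
## completeness invariants the downstream algorithms assume.

.validateExpressionMatrix <- function(m, what = "expression matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must carry sample ids (rownames) and gene ids (colnames)")
  if (anyDuplicated(colnames(m)))
    stop(what, ": duplicate gene ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyDuplicated(rownames(m)))
    stop(what, ": duplicate sample ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("%s: missing or non-numeric value at sample '%s', gene '%s'",
                 what, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  invisible(m)
}

#' Read an expression matrix (samples x genes) from delimited text
#'
#' Expects a header row of gene identifiers and a first column of sample
#' identifiers. Values must be complete and numeric: a missing (\code{NA})
#' or non-numeric cell is a parse error naming the offending sample and
#' gene; ragged rows are reported with their line number.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param sep field delimiter; `"\t"` by default, use `","` for CSV.
#' @return numeric matrix with sample ids as rownames, gene ids as colnames.
#' @export
readExpressionMatrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr))
    stop("'", path, "': duplicate gene ids in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "", comment.char = ""),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(df) < 2) stop("expected a sample-id column plus gene columns: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- hdr
  if (!is.numeric(m)) {
    num <- suppressWarnings(
      matrix(as.numeric(m), nrow = nrow(m), ncol = ncol(m),
             dimnames = dimnames(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("parse error in '%s': non-numeric cell '%s' at sample '%s', gene '%s'",
                   path, m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                   colnames(m)[bad[1, 2]]))
    m <- num
  }
  rownames(m) <- ids
  .validateExpressionMatrix(m, paste0("'", path, "'"))
  m
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [readExpressionMatrix()]: header row of gene ids, first column
#' of sample ids. Round-trips values at full double precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param sep field delimiter.
#' @export
writeExpressionMatrix <- function(m, path, sep = "\t") {
  .validateExpressionMatrix(m)
  df <- data.frame(sample_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug response vector (sample id, IC50 value)
#'
#' Two-column delimited file; a header line is detected and skipped when the
#' second field of the first line is not numeric. Duplicate sample ids are
#' rejected.
#'
#' @inheritParams readExpressionMatrix
#' @return named numeric vector of responses.
#' @export
readResponseVector <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- length(first) >= 2 &&
    is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("expected two columns (sample id, value): ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(vals)))
    stop(sprintf("parse error in '%s': non-numeric response for sample '%s'",
                 path, ids[which(is.na(vals))[1]]))
  names(vals) <- ids
  vals
}

#' Read binary clinical labels (sample id, label, optional category)
#'
#' Labels are 1 = resistant / non-responder, 0 = sensitive / responder. An
#' optional third column holds a fine-grained response category (e.g. CR,
#' PR, MR, NC, PD), kept as the \code{"category"} attribute.
#'
#' @inheritParams readExpressionMatrix
#' @return named integer vector of 0/1 labels.
#' @export
readClinicalLabels <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- length(first) >= 2 &&
    is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in '", path, "'")
  lab <- suppressWarnings(as.integer(df[[2]]))
  if (any(is.na(lab)) || !all(lab %in% c(0L, 1L)))
    stop("labels in '", path, "' must be binary 0/1")
  names(lab) <- ids
  if (ncol(df) >= 3) {
    cat. <- as.character(df[[3]])
    names(cat.) <- ids
    attr(lab, "category") <- cat.
  }
  lab
}

#' Align an auxiliary vector to the row order of an expression matrix
#'
#' Reorders a named response or label vector to the sample order of
#' \code{expr}. The sample sets must match exactly; any discrepancy is an
#' error listing the missing ids. Idempotent.
#'
#' @param expr expression matrix (samples x genes) with sample rownames.
#' @param aux named vector (responses or labels) over the same samples.
#' @return \code{aux} reordered to \code{rownames(expr)}.
#' @export
alignSamples <- function(expr, aux) {
  ids <- rownames(expr)
  if (is.null(ids)) stop("expression matrix has no sample ids")
  if (is.null(names(aux))) stop("auxiliary vector has no sample ids")
  missingAux <- setdiff(ids, names(aux))
  extraAux <- setdiff(names(aux), ids)
  if (length(missingAux) || length(extraAux))
    stop("sample sets do not match; missing from aux: [",
         paste(missingAux, collapse = ", "), "]; not in expression matrix: [",
         paste(extraAux, collapse = ", "), "]")
  out <- aux[ids]
  cat. <- attr(aux, "category")
  if (!is.null(cat.)) attr(out, "category") <- cat.[ids]
  out
}

#' Check that a test matrix presents the training gene set in training order
#'
#' The transfer setting requires identical gene columns in identical order.
#' By default a mismatch is an error; with \code{reorder = TRUE} a test
#' matrix whose columns are a permutation of the training genes is reordered
#' to match.
#'
#' @param train,test expression matrices (samples x genes).
#' @param reorder reorder test columns by gene id instead of failing.
#' @return the (possibly reordered) test matrix, invisibly unchanged when
#'   already aligned.
#' @export
checkGeneCompatibility <- function(train, test, reorder = FALSE) {
  gt <- colnames(train); ge <- colnames(test)
  if (identical(gt, ge)) return(test)
  if (!setequal(gt, ge))
    stop("gene sets differ between training and test matrices; missing in test: [",
         paste(utils::head(setdiff(gt, ge), 5), collapse = ", "), "]")
  if (!reorder)
    stop("test genes are a permutation of training genes; pass reorder = TRUE to reorder")
  test[, gt, drop = FALSE]
}

#' Write per-tumor predictions as two-column TSV
#'
#' @param predictions named numeric vector (sample id -> predicted response).
#' @param path output path.
#' @param sep field delimiter.
#' @export
writePredictions <- function(predictions, path, sep = "\t") {
  df <- data.frame(sample_id = names(predictions),
                   predicted_response = as.numeric(predictions),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
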