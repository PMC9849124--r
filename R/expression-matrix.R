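#' Log-transform a count matrix
#'
#' Converts non-negative counts to the log2 scale used throughout the package,
#' `log2(count + pseudocount)`. All model fitting, PRPS averaging and most
#' diagnostics operate on this scale.
#'
#' @param counts Numeric matrix of non-negative counts, assays in rows and
#'   genes in columns, with row and column names.
#' @param pseudocount Positive offset added before taking logs. Default 1.
#' @return Numeric matrix of the same dimensions on the log2 scale.
#' @export
log_counts <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be finite and non-negative")
  }
  if (pseudocount <= 0) stop("`pseudocount` must be positive")
  log2(counts + pseudocount)
}

# Validate an assays x genes expression matrix; returns the matrix invisibly.
validate_expression <- function(Y, min_assays = 2L) {
  if (!is.matrix(Y) || !is.numeric(Y)) stop("expression data must be a numeric matrix")
  if (nrow(Y) < min_assays) stop("need at least ", min_assays, " assays (rows)")
  if (ncol(Y) < 1L) stop("need at least one gene (column)")
  if (any(!is.finite(Y))) stop("expression matrix contains non-finite values")
  if (!is.null(rownames(Y)) && anyDuplicated(rownames(Y)))
    stop("duplicated assay identifiers in rownames")
  if (!is.null(colnames(Y)) && anyDuplicated(colnames(Y)))
    stop("duplicated gene identifiers in colnames")
  invisible(Y)
}

# Resolve a control-gene specification (character ids or logical/integer index)
# against the columns of Y; errors on empty or unknown genes.
resolve_controls <- function(Y, controls) {
  if (is.null(controls) || length(controls) == 0L) stop("control gene set is empty")
  if (is.character(controls)) {
    if (is.null(colnames(Y))) stop("Y has no gene names; pass controls as an index")
    idx <- match(unique(controls), colnames(Y))
    if (anyNA(idx)) {
      stop("control genes absent from the matrix: ",
           paste(utils::head(unique(controls)[is.na(idx)], 5L), collapse = ", "))
    }
  } else if (is.logical(controls)) {
    if (length(controls) != ncol(Y)) stop("logical control index has wrong length")
    idx <- which(controls)
  } else {
    idx <- as.integer(controls)
    if (any(idx < 1L | idx > ncol(Y))) stop("control index out of range")
    idx <- unique(idx)
  }
  if (length(idx) == 0L) stop("control gene set is empty")
  idx
}

# Moore-Penrose pseudo-inverse with a relative singular-value cutoff.
pinv <- function(A, rtol = 1e-12) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}
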