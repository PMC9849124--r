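#' Read a count or expression matrix
#'
#' Reads TSV/CSV (dense, with row and column ids) or MatrixMarket `.mtx`
#' triplets with sidecar id files (`<stem>.rows` = assay ids, `<stem>.cols`
#' = gene ids, one per line). The in-memory convention is assays x genes;
#' files with genes in rows are transposed on request.
#'
#' @param path File path; format inferred from the extension unless `format`
#'   is given.
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @param genes_in_rows Is the file genes x assays? Transposed after reading.
#' @return Numeric matrix, assays x genes, with ids as dimnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        genes_in_rows = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    rows_file <- paste0(stem, ".rows"); cols_file <- paste0(stem, ".cols")
    if (!file.exists(rows_file) || !file.exists(cols_file)) {
      stop("sidecar id files not found: ", rows_file, " / ", cols_file)
    }
    M <- as.matrix(Matrix::readMM(path))
    row_ids <- readLines(rows_file); col_ids <- readLines(cols_file)
    if (length(row_ids) != nrow(M) || length(col_ids) != ncol(M)) {
      stop("sidecar id files do not match the matrix dimensions")
    }
    dimnames(M) <- list(row_ids, col_ids)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    M <- as.matrix(df)
  }
  if (genes_in_rows) M <- t(M)
  if (anyDuplicated(rownames(M)) || anyDuplicated(colnames(M))) {
    stop("duplicated ids in ", path)
  }
  storage.mode(M) <- "double"
  M
}

#' Write a count or expression matrix
#'
#' Inverse of [read_counts()]: dense TSV/CSV with ids, or MatrixMarket
#' triplets (1-based indices per the standard) plus `.rows`/`.cols` sidecars.
#'
#' @param x Matrix, assays x genes, with dimnames.
#' @param path Output path; format inferred from extension unless given.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("auto", "tsv", "csv", "mtx"),
                         genes_in_rows = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", "tsv")
  }
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("matrix must have row and column ids")
  }
  out <- if (genes_in_rows) t(x) else x
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(out, sparse = TRUE), path)
    writeLines(rownames(out), paste0(stem, ".rows"))
    writeLines(colnames(out), paste0(stem, ".cols"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(id = rownames(out), out, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-assay sample metadata
#'
#' TSV (or CSV) with one row per assay and an `assay_id` column.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Tibble with `assay_id` first.
#' @export
read_metadata <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"assay_id" %in% names(df)) stop("metadata must have an `assay_id` column")
  if (anyDuplicated(df$assay_id)) stop("duplicated assay_id in ", path)
  tibble::as_tibble(df) |> dplyr::relocate("assay_id")
}

#' Read gene sets (GMT or one id per line)
#'
#' GMT lines are `name <tab> description <tab> gene1 <tab> gene2 ...`; a
#' malformed line (fewer than 3 fields) is an error naming the line number.
#' Plain files (extension other than `.gmt`) are read as one gene id per
#' line and returned as a single unnamed set.
#'
#' @param path File path.
#' @return Named list of character vectors (GMT), or a character vector
#'   (plain list).
#' @export
read_geneset <- function(path) {
  if (tolower(tools::file_ext(path)) == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- lapply(seq_along(lines), function(i) {
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(fields) < 3L) {
        stop("malformed GMT line ", i, " in ", path,
             ": expected at least 3 tab-separated fields")
      }
      stats::setNames(list(unique(fields[-(1:2)])), fields[1])
    })
    do.call(c, sets)
  } else {
    ids <- trimws(readLines(path))
    ids[nzchar(ids)]
  }
}

#' Write gene sets
#'
#' A named list becomes a GMT file (description field `"na"`); a character
#' vector becomes one id per line.
#'
#' @param x Named list of character vectors, or a character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geneset <- function(x, path) {
  if (is.list(x)) {
    stopifnot(!is.null(names(x)))
    writeLines(vapply(names(x), function(nm) {
      paste(c(nm, "na", x[[nm]]), collapse = "\t")
    }, character(1)), path)
  } else {
    writeLines(as.character(x), path)
  }
  invisible(path)
}

#' Write an assessment or filter report to disk
#'
#' Each tabular element becomes `<dir>/<name>.tsv`; scalars and thresholds
#' are collected into `<dir>/summary.json`.
#'
#' @param report An `assessment_report` or `filter_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary <- list()
  for (nm in names(report)) {
    el <- report[[nm]]
    if (is.data.frame(el)) {
      utils::write.table(el, file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is.list(el) && !inherits(el, "pca_scores")) {
      summary[[nm]] <- el
    } else if (is.atomic(el) && length(el) == 1L) {
      summary[[nm]] <- el
    }
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
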