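#' Filter assays by plate size and library-size outliers
#'
#' Two sequential rules: (1) drop every assay on a plate with fewer than
#' `min_plate_size` assays; (2) among the survivors, drop assays whose log2
#' library size lies more than `mad_multiplier` median absolute deviations
#' below the median log2 library size. The MAD uses the 1.4826
#' normal-consistency constant by default (`mad_constant`). Library size is
#' the assay's total count over the genes currently in the matrix.
#'
#' @param counts Matrix of raw counts, assays x genes.
#' @param meta Data frame with `assay_id` and the plate column.
#' @param plate Name of the plate column in `meta`.
#' @param min_plate_size Minimum assays per plate (default 3).
#' @param mad_multiplier How many MADs below the median triggers removal
#'   (default 3).
#' @param mad_constant Consistency constant of the MAD (default 1.4826).
#' @return List with `counts`, `meta` (filtered, same order) and `report`, a
#'   `filter_report` whose `assays_removed` tibble carries one reason
#'   (`small-plate` or `low-library-size`) per removal.
#' @export
filter_assays <- function(counts, meta, plate, min_plate_size = 3L,
                          mad_multiplier = 3, mad_constant = 1.4826) {
  counts <- as.matrix(counts)
  meta <- check_prps_meta(counts, meta, plate)
  meta <- meta[match(rownames(counts), meta$assay_id), ]
  if (anyNA(meta$assay_id)) stop("`meta` must cover every assay in `counts`")

  plate_sizes <- table(meta[[plate]])
  small <- meta$assay_id[meta[[plate]] %in%
                           names(plate_sizes)[plate_sizes < min_plate_size]]

  keep1 <- !(rownames(counts) %in% small)
  ls <- log2(rowSums(counts[keep1, , drop = FALSE]) + 1)
  med <- stats::median(ls)
  mad <- stats::mad(ls, constant = mad_constant)
  low <- names(ls)[ls < med - mad_multiplier * mad]

  removed <- tibble::tibble(
    assay_id = c(small, low),
    reason = rep(c("small-plate", "low-library-size"),
                 c(length(small), length(low))))
  keep <- setdiff(rownames(counts), removed$assay_id)
  if (length(keep) == 0L) stop("all assays removed by filtering")

  report <- structure(list(
    assays_removed = removed,
    genes_removed = tibble::tibble(gene_id = character(), reason = character()),
    thresholds = list(min_plate_size = min_plate_size,
                      mad_multiplier = mad_multiplier,
                      mad_constant = mad_constant),
    order = c("small-plate", "low-library-size")),
    class = "filter_report")
  list(counts = counts[keep, , drop = FALSE],
       meta = meta[match(keep, meta$assay_id), ],
       report = report)
}

#' Filter lowly expressed genes
#'
#' Keeps genes with at least `min_count` raw counts in at least
#' `min_fraction` of assays (boundaries inclusive). With `groups` given, the
#' rule is applied within the smallest group (e.g. the smallest biological
#' subpopulation within a time stratum), so that genes expressed only in a
#' small subtype are not discarded.
#'
#' @param counts Matrix of non-negative raw counts, assays x genes.
#' @param min_count Count threshold (default 15).
#' @param min_fraction Fraction-of-assays threshold (default 0.20).
#' @param groups Optional factor-like vector (one per assay); the rule is
#'   evaluated on the assays of the smallest group.
#' @return List with `counts` (columns filtered) and `report`
#'   (`filter_report` with `genes_removed`, reason `low-expression`).
#' @export
filter_genes <- function(counts, min_count = 15L, min_fraction = 0.20,
                         groups = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("`counts` must be non-negative")
  sub <- counts
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(counts))
    f <- factor(groups)
    smallest <- names(which.min(table(f)))
    sub <- counts[f == smallest, , drop = FALSE]
  }
  frac <- colMeans(sub >= min_count)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("all genes removed by the low-expression filter")
  gene_ids <- colnames(counts) %||% paste0("gene_", seq_len(ncol(counts)))
  report <- structure(list(
    assays_removed = tibble::tibble(assay_id = character(), reason = character()),
    genes_removed = tibble::tibble(gene_id = gene_ids[!keep],
                                   reason = "low-expression"),
    thresholds = list(min_count = min_count, min_fraction = min_fraction,
                      groups = !is.null(groups)),
    order = "low-expression"),
    class = "filter_report")
  list(counts = counts[, keep, drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report\n")
  if (nrow(x$assays_removed)) {
    tab <- table(x$assays_removed$reason)
    cat("  assays removed:", nrow(x$assays_removed),
        paste0("(", paste(names(tab), tab, sep = ": ", collapse = ", "), ")"), "\n")
  } else cat("  assays removed: 0\n")
  if (nrow(x$genes_removed)) {
    cat("  genes removed:", nrow(x$genes_removed), "(low-expression)\n")
  } else cat("  genes removed: 0\n")
  cat("  thresholds:", paste(names(x$thresholds),
                             unlist(lapply(x$thresholds, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}
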