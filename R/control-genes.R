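#' Per-gene one-way ANOVA F statistics
#'
#' One-way ANOVA of each gene's expression on a factor (subtype, plate, flow
#' cell chemistry, ...), vectorized across genes. Genes with large F are
#' deemed affected by the factor; genes with small F against the biology of
#' interest are candidate negative controls. A gene with zero between- and
#' zero within-group variance (constant gene) returns F = 0 by convention.
#'
#' @param Y Numeric matrix, assays x genes (any expression scale).
#' @param labels Factor-like vector, one level per assay; every level needs
#'   at least 2 assays.
#' @return Named numeric vector of F statistics, one per gene, with
#'   attributes `df1` and `df2`.
#' @export
anova_f_per_gene <- function(Y, labels) {
  Y <- as.matrix(Y)
  f <- droplevels(factor(labels))
  if (nrow(Y) != length(f)) stop("`labels` must have one value per assay")
  if (nlevels(f) < 2L) stop("need at least 2 factor levels")
  cnt <- as.vector(table(f))
  if (any(cnt < 2L)) {
    stop("every level needs >= 2 assays (offending: ",
         paste(levels(f)[cnt < 2L], collapse = ", "), ")")
  }
  m <- nrow(Y); g <- nlevels(f)
  grand <- colMeans(Y)
  group_means <- rowsum(Y, f) / cnt
  ss_between <- colSums(cnt * sweep(group_means, 2, grand)^2)
  ss_total <- colSums(sweep(Y, 2, grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- g - 1L; df2 <- m - g
  Fstat <- (ss_between / df1) / (ss_within / df2)
  Fstat[ss_between <= .Machine$double.eps * ss_total] <- 0
  Fstat[ss_within <= .Machine$double.eps * ss_total & ss_between > 0] <- Inf
  Fstat[ss_total == 0] <- 0 # constant gene
  structure(stats::setNames(Fstat, colnames(Y)), df1 = df1, df2 = df2)
}

#' Per-gene Spearman correlation with a covariate
#'
#' Tie-corrected Spearman rank correlation of every gene with a per-assay
#' covariate such as (log) library size, tumor purity, an RLE median or a
#' housekeeping average. Constant genes get rho = 0 and are listed in the
#' `constant` attribute.
#'
#' @param Y Numeric matrix, assays x genes.
#' @param covariate Numeric vector, one value per assay; must not be constant.
#' @return Named numeric vector of correlations in \[-1, 1\].
#' @export
spearman_per_gene <- function(Y, covariate) {
  Y <- as.matrix(Y)
  if (nrow(Y) != length(covariate)) stop("`covariate` must have one value per assay")
  if (any(!is.finite(covariate))) stop("`covariate` must be finite")
  if (stats::sd(covariate) == 0) stop("`covariate` is constant")
  rho <- suppressWarnings(stats::cor(Y, covariate, method = "spearman"))[, 1]
  constant <- !is.finite(rho)
  rho[constant] <- 0
  structure(stats::setNames(rho, colnames(Y)), constant = which(constant))
}

#' Per-assay mean expression of a housekeeping gene list
#'
#' The average log-scale expression of a supplied housekeeping set, used as a
#' per-assay covariate: genes whose expression tracks this average closely
#' behave like housekeeping genes and are control candidates.
#'
#' @param Y Log-scale matrix, assays x genes.
#' @param housekeeping Character vector of gene ids; must intersect the
#'   matrix's genes.
#' @return Named numeric vector, one mean per assay.
#' @export
housekeeping_covariate <- function(Y, housekeeping) {
  Y <- as.matrix(Y)
  idx <- intersect(housekeeping, colnames(Y))
  if (length(idx) == 0L) stop("no housekeeping genes found in the matrix")
  rowMeans(Y[, idx, drop = FALSE])
}

#' Define one negative-control selection criterion
#'
#' A criterion scores every gene with one statistic (one-way ANOVA F against a
#' factor, or Spearman correlation with a covariate) on a designated matrix,
#' then keeps genes by a threshold on the statistic or by rank. Different
#' criteria may use different matrices: e.g. biology-F on normalized data but
#' library-size correlation on raw counts.
#'
#' @param name Short label used in reports and error messages.
#' @param statistic `"anova_f"` or `"spearman"`.
#' @param variable The factor (for `anova_f`) or numeric covariate (for
#'   `spearman`), one value per assay.
#' @param direction One of `"keep_low"`, `"keep_high"`, `"keep_abs_low"`,
#'   `"keep_abs_high"`; `abs` variants compare `|statistic|`.
#' @param threshold Numeric cutoff; `keep_low` keeps statistic < threshold,
#'   `keep_high` keeps statistic > threshold (strict, matching recipes such
#'   as F < 20 or rho > 0.9). Exactly one of `threshold` / `rank_count`.
#' @param rank_count Integer; keep the `rank_count` most extreme genes in the
#'   stated direction, ties broken by gene id.
#' @param data Optional matrix (assays x genes) this criterion is evaluated
#'   on; default the matrix passed to [select_ncg()].
#' @return A `gene_criterion` object.
#' @export
gene_criterion <- function(name, statistic = c("anova_f", "spearman"),
                           variable, direction = c("keep_low", "keep_high",
                                                   "keep_abs_low", "keep_abs_high"),
                           threshold = NULL, rank_count = NULL, data = NULL) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  if (is.null(threshold) == is.null(rank_count)) {
    stop("exactly one of `threshold` and `rank_count` must be set")
  }
  structure(list(name = name, statistic = statistic, variable = variable,
                 direction = direction, threshold = threshold,
                 rank_count = rank_count, data = data),
            class = "gene_criterion")
}

criterion_statistic <- function(Y, crit) {
  mat <- if (is.null(crit$data)) Y else as.matrix(crit$data)
  if (!identical(colnames(mat), colnames(Y))) {
    stop("criterion '", crit$name, "': its matrix has a different gene set/order")
  }
  switch(crit$statistic,
         anova_f = as.numeric(anova_f_per_gene(mat, crit$variable)),
         spearman = as.numeric(spearman_per_gene(mat, crit$variable)))
}

criterion_pass <- function(stat, crit, gene_ids) {
  val <- if (grepl("abs", crit$direction)) abs(stat) else stat
  # round to stabilize boundary genes across platforms
  val <- round(val, 12)
  lowish <- crit$direction %in% c("keep_low", "keep_abs_low")
  if (!is.null(crit$threshold)) {
    if (lowish) val < crit$threshold else val > crit$threshold
  } else {
    nc <- min(crit$rank_count, length(val))
    ord <- if (lowish) order(val, gene_ids) else order(-val, gene_ids)
    pass <- logical(length(val))
    pass[ord[seq_len(nc)]] <- TRUE
    pass
  }
}

#' Select negative control genes by intersecting criteria
#'
#' Evaluates every criterion and keeps the genes passing all of them (the
#' recipes in this field are conjunctions: low biology-F AND low purity
#' correlation AND high housekeeping correlation, etc.). Selection is
#' deterministic, with rank ties broken by gene id.
#'
#' @param Y Matrix, assays x genes, used for criteria without their own
#'   `data`.
#' @param criteria A `gene_criterion` or list of them.
#' @return Character vector of selected gene ids, with attribute `summary`: a
#'   tibble of per-criterion pass counts. Errors if the intersection is
#'   empty, naming the first criterion whose removal would not help (the
#'   first fully exclusive one if any).
#' @export
select_ncg <- function(Y, criteria) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) stop("`Y` must have gene ids as colnames")
  if (inherits(criteria, "gene_criterion")) criteria <- list(criteria)
  stopifnot(length(criteria) > 0,
            all(vapply(criteria, inherits, logical(1), "gene_criterion")))
  gene_ids <- colnames(Y)
  pass <- vapply(criteria, function(cr) {
    criterion_pass(criterion_statistic(Y, cr), cr, gene_ids)
  }, logical(length(gene_ids)))
  pass <- matrix(pass, nrow = length(gene_ids))
  n_pass <- colSums(pass)
  selected <- gene_ids[rowSums(pass) == length(criteria)]
  summary <- tibble::tibble(
    criterion = vapply(criteria, `[[`, character(1), "name"),
    statistic = vapply(criteria, `[[`, character(1), "statistic"),
    n_pass = as.integer(n_pass))
  if (length(selected) == 0L) {
    culprit <- if (any(n_pass == 0L)) summary$criterion[which(n_pass == 0L)[1]] else
      summary$criterion[which.min(n_pass)]
    stop("no gene passes all criteria; most exclusive criterion: '", culprit, "'")
  }
  structure(selected, summary = summary)
}
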