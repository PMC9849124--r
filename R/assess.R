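#' Relative log expression (RLE) summaries
#'
#' For gene g in assay i the RLE value is the log expression minus that gene's
#' median log expression across assays. In well-normalized data the per-assay
#' RLE medians sit near zero with comparable IQRs; systematic deviations, and
#' correlation of the medians with known factors, flag unwanted variation.
#'
#' @param x Matrix, assays x genes: raw counts (default) or already-logged
#'   values with `log = FALSE`.
#' @param log Log2-transform `x` with `pseudocount` first? Default TRUE.
#' @param pseudocount Offset for the log transform.
#' @return Tibble with `assay_id`, `median`, `iqr`; the full RLE matrix is
#'   attached as attribute `"rle"`.
#' @export
rle_stats <- function(x, log = TRUE, pseudocount = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("RLE needs at least 2 assays")
  L <- if (log) log_counts(x, pseudocount) else x
  rle <- sweep(L, 2, apply(L, 2, stats::median))
  out <- tibble::tibble(
    assay_id = rownames(rle) %||% paste0("assay_", seq_len(nrow(rle))),
    median = apply(rle, 1, stats::median),
    iqr = apply(rle, 1, stats::IQR))
  attr(out, "rle") <- rle
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal component scores of an expression matrix
#'
#' PCA on gene-wise mean-centered values (no scaling), via SVD. Components
#' are ordered by decreasing variance, with a deterministic sign convention:
#' each component's largest-magnitude gene loading is positive.
#'
#' @param Y Matrix, assays x genes, log scale.
#' @param n_components Number of components (default
#'   `min(10, m - 1, n)`).
#' @return A `pca_scores` object: list with `scores` (m x n_components),
#'   `sdev`, `var_explained` (fractions) and `loadings` (n x n_components).
#' @export
pca_scores <- function(Y, n_components = NULL) {
  Y <- as.matrix(Y)
  m <- nrow(Y)
  kmax <- min(m - 1L, ncol(Y))
  n_components <- as.integer(n_components %||% min(10L, kmax))
  if (n_components > kmax) stop("`n_components` exceeds min(m - 1, n)")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (max(abs(Yc)) == 0) stop("matrix has zero variance")
  s <- svd(Yc, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- s$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(s$u, 2, flip * s$d[seq_len(n_components)], `*`)
  loadings <- sweep(s$v, 2, flip, `*`)
  dimnames(scores) <- list(rownames(Y), paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(Y), colnames(scores))
  structure(list(scores = scores,
                 sdev = s$d[seq_len(n_components)] / sqrt(m - 1),
                 var_explained = s$d^2 / sum(s$d^2),
                 loadings = loadings),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat("PCA scores:", nrow(x$scores), "assays x", ncol(x$scores), "components\n")
  cat("  variance explained:",
      paste0(signif(100 * utils::head(x$var_explained, 5), 3), "%", collapse = ", "),
      "\n")
  invisible(x)
}

get_scores <- function(scores) {
  if (inherits(scores, "pca_scores")) scores$scores else as.matrix(scores)
}

#' R-squared of a covariate on cumulative principal components
#'
#' Ordinary least squares of the covariate on the first k score columns, for
#' k = 1..k_max. A strong fit means the leading components — the dominant
#' variation in the data — track the covariate (library size, purity, RLE
#' median, ...). Non-decreasing in k.
#'
#' @param scores A `pca_scores` object or score matrix (assays x components).
#' @param covariate Numeric vector, one value per assay.
#' @param k_max How many cumulative components (default 5).
#' @return Numeric vector of R-squared values, names `"1:k"`.
#' @export
r2_cumulative_pcs <- function(scores, covariate, k_max = 5L) {
  S <- get_scores(scores)
  if (length(covariate) != nrow(S)) stop("`covariate` must have one value per assay")
  if (any(!is.finite(covariate))) stop("`covariate` must be finite")
  if (k_max > ncol(S)) stop("`k_max` exceeds the available components")
  sst <- sum((covariate - mean(covariate))^2)
  if (sst == 0) stop("`covariate` is constant")
  vapply(seq_len(k_max), function(k) {
    fit <- stats::lm.fit(cbind(1, S[, seq_len(k), drop = FALSE]), covariate)
    1 - sum(fit$residuals^2) / sst
  }, numeric(1)) |> stats::setNames(paste0("1:", seq_len(k_max)))
}

#' Rozeboom squared vector correlation
#'
#' Summarizes the canonical correlations rho_1..rho_s between a set of score
#' columns and a grouping as `1 - prod(1 - rho_i^2)`, in \[0, 1\]. The grouping
#' is dummy-coded with one level dropped; when `variable` is a single numeric
#' covariate the quantity reduces exactly to the regression R-squared.
#'
#' @param scores A `pca_scores` object or score matrix (assays x k).
#' @param variable Factor-like labels (dummy-coded) or a numeric vector /
#'   matrix of covariates.
#' @return Squared vector correlation in \[0, 1\].
#' @export
vector_correlation <- function(scores, variable) {
  S <- get_scores(scores)
  if (is.numeric(variable) && !is.factor(variable)) {
    D <- as.matrix(variable)
  } else {
    f <- droplevels(factor(variable))
    if (nlevels(f) < 2L) stop("grouping needs at least 2 levels with assays")
    D <- stats::model.matrix(~f)[, -1, drop = FALSE]
  }
  if (nrow(D) != nrow(S)) stop("`variable` must have one value per assay")
  cc <- stats::cancor(S, D)
  1 - prod(1 - pmin(cc$cor, 1)^2)
}

#' Mean silhouette coefficient of a labeling in PC space
#'
#' Euclidean-distance silhouette of each assay against a labeling, averaged.
#' High values mean the labels form tight, separated clusters — desirable for
#' biology, undesirable for batch (good batch mixing gives values near 0).
#' Singleton clusters take silhouette 0 (the standard convention).
#'
#' @param scores A `pca_scores` object or score matrix.
#' @param labels Factor-like vector, at least 2 distinct labels.
#' @param n_pcs Number of leading score columns to use (default
#'   `min(3, ncol)`).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_mean <- function(scores, labels, n_pcs = NULL) {
  S <- get_scores(scores)
  n_pcs <- as.integer(n_pcs %||% min(3L, ncol(S)))
  f <- droplevels(factor(labels))
  if (nlevels(f) < 2L) stop("silhouette needs at least 2 distinct labels")
  sil <- cluster::silhouette(as.integer(f),
                             dist = stats::dist(S[, seq_len(n_pcs), drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Adjusted Rand index between k-means clusters and labels
#'
#' Clusters the first `n_pcs` principal component scores with k-means
#' (`n_clusters` centers, 25 restarts, seeded) and scores the chance-corrected
#' agreement of the clustering with reference labels. Used for biology
#' separation (higher better) and batch mixing (lower better); invariant to
#' renaming labels or clusters.
#'
#' @param scores A `pca_scores` object or score matrix.
#' @param labels Reference labels.
#' @param n_clusters Number of k-means clusters (default: number of label
#'   levels).
#' @param seed Integer seed for the k-means restarts (required).
#' @param n_pcs Leading score columns used (default `min(3, ncol)`).
#' @param nstart k-means restarts (default 25).
#' @return Adjusted Rand index (1 = perfect agreement, ~0 = chance).
#' @export
ari_by_label <- function(scores, labels, n_clusters = NULL, seed,
                         n_pcs = NULL, nstart = 25L) {
  S <- get_scores(scores)
  f <- droplevels(factor(labels))
  n_clusters <- as.integer(n_clusters %||% nlevels(f))
  if (n_clusters < 2L) stop("`n_clusters` must be at least 2")
  if (nrow(S) < n_clusters) stop("fewer assays than clusters")
  n_pcs <- as.integer(n_pcs %||% min(3L, ncol(S)))
  km <- with_seed(seed, stats::kmeans(S[, seq_len(n_pcs), drop = FALSE],
                                      centers = n_clusters, nstart = nstart))
  mclust::adjustedRandIndex(km$cluster, f)
}

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed)) stop("a `seed` is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Per-gene two-group differential expression p-values
#'
#' Two-sample Wilcoxon rank-sum test of every gene between two groups (e.g.
#' low vs high library size, or batches), using the normal approximation with
#' continuity correction. Between groups that differ only technically, the
#' p-value histogram should be uniform; an excess below 0.05 quantifies
#' unwanted variation. `paired = TRUE` switches to the signed-rank variant
#' for genuinely paired designs.
#'
#' @param x Matrix, assays x genes (rank tests are invariant to monotone
#'   transforms, so raw or log scale give identical results).
#' @param group Two-level factor-like vector, both levels with >= 2 assays
#'   (equal sizes required when `paired = TRUE`).
#' @param paired Use the signed-rank test on assay pairs (matched by order
#'   within group). Default FALSE.
#' @return List with `p_values` (named per-gene vector) and `fraction_sig`,
#'   the unadjusted fraction below 0.05.
#' @export
de_pvalues <- function(x, group, paired = FALSE) {
  x <- as.matrix(x)
  f <- droplevels(factor(group))
  if (nlevels(f) != 2L) stop("`group` must have exactly 2 levels")
  if (any(table(f) < 2L)) stop("both groups need >= 2 assays")
  i1 <- which(f == levels(f)[1]); i2 <- which(f == levels(f)[2])
  if (paired && length(i1) != length(i2)) stop("paired test needs equal group sizes")
  p <- apply(x, 2, function(v) {
    suppressWarnings(stats::wilcox.test(v[i1], v[i2], paired = paired,
                                        exact = FALSE, correct = TRUE)$p.value)
  })
  p[is.na(p)] <- 1 # all-tied gene: no evidence against the null
  list(p_values = p, fraction_sig = mean(p < 0.05))
}

#' Partial correlation controlling for one variable
#'
#' Correlation between x and y with the (linear, or rank-linear for the
#' Spearman flavor) contribution of z removed:
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`. Used to show that a
#' gene-gene correlation is explained by a confounder such as tumor purity.
#'
#' @param x,y,z Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"` (rank-transforms
#'   first).
#' @return The partial correlation; `NA` with attribute `undefined = TRUE`
#'   (and a warning) when z is perfectly correlated with x or y.
#' @export
partial_correlation <- function(x, y, z, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) == length(z))
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  denom <- (1 - r_xz^2) * (1 - r_yz^2)
  if (denom <= .Machine$double.eps) {
    warning("partial correlation undefined: z is collinear with x or y")
    return(structure(NA_real_, undefined = TRUE))
  }
  (r_xy - r_xz * r_yz) / sqrt(denom)
}

#' Rank-based single-sample signature score
#'
#' Scores every assay against a gene set of up-regulated genes: genes are
#' ranked within the assay (average ranks for ties), the set's mean rank is
#' taken, and the result is normalized by the analytic minimum `(s + 1) / 2`
#' and maximum `n - (s - 1) / 2` achievable mean rank for a set of size s
#' among n genes, so the score spans \[0, 1\]. Invariant under any monotone
#' transform of an assay's values. With `s == n` the score is the constant
#' 0.5.
#'
#' @param Y Matrix, assays x genes, log scale.
#' @param geneset Character vector of gene ids (an up-set); must intersect
#'   the matrix's genes.
#' @return Named numeric vector of scores in \[0, 1\], one per assay.
#' @export
signature_score <- function(Y, geneset) {
  Y <- as.matrix(Y)
  idx <- which(colnames(Y) %in% geneset)
  if (length(idx) == 0L) stop("gene set does not intersect the matrix's genes")
  n <- ncol(Y); s <- length(idx)
  mean_rank <- apply(Y, 1, function(v) mean(rank(v)[idx]))
  lo <- (s + 1) / 2; hi <- n - (s - 1) / 2
  if (hi == lo) return(stats::setNames(rep(0.5, nrow(Y)), rownames(Y)))
  stats::setNames((mean_rank - lo) / (hi - lo), rownames(Y))
}

#' Tumor purity score from stromal and immune signatures
#'
#' One minus the signature score of the combined stromal and immune gene
#' sets: bulk tumor assays rich in stromal/immune transcripts score low.
#'
#' @param Y Matrix, assays x genes, log scale.
#' @param stromal,immune Character vectors of signature gene ids.
#' @return Named numeric vector of purity scores in \[0, 1\].
#' @export
purity_score <- function(Y, stromal, immune = character(0)) {
  1 - signature_score(Y, union(stromal, immune))
}

#' Assemble the full unwanted-variation assessment report
#'
#' Runs the global diagnostics (RLE summaries, PCA, cumulative-PC regression
#' and vector correlation, silhouette, ARI) and gene-level diagnostics
#' (per-gene Spearman/ANOVA association, two-group DE fractions, signature
#' scores) against the supplied unwanted-variation covariates and factors.
#'
#' @param Y Matrix, assays x genes, log scale (already normalized or not).
#' @param covariates Named list of numeric per-assay vectors (e.g.
#'   `list(library_size = ..., purity = ...)`).
#' @param factors Named list of factor-like per-assay vectors (e.g.
#'   `list(plate = ..., biology = ...)`).
#' @param genesets Optional named list of gene-id vectors to score per assay.
#' @param de_groups Optional named list of two-level groupings for DE
#'   fractions.
#' @param k_max Cumulative components for regressions (default 5).
#' @param seed Seed for the ARI clustering step.
#' @param counts Optional raw count matrix for the RLE table (default:
#'   treat `Y` as logged values).
#' @return An `assessment_report`: named list of tibbles
#'   (`rle_per_assay`, `pc_variance`, `r2_by_cumulative_pc`,
#'   `vector_correlation_by_cumulative_pc`, `cluster_metrics`, `gene_assoc`,
#'   `de_fractions`, `score_per_assay`), plus the `pca_scores` object.
#' @export
assess_normalization <- function(Y, covariates = list(), factors = list(),
                                 genesets = list(), de_groups = list(),
                                 k_max = 5L, seed = 1L, counts = NULL) {
  Y <- as.matrix(Y)
  pca <- pca_scores(Y, n_components = min(10L, nrow(Y) - 1L, ncol(Y)))
  k_max <- min(k_max, ncol(pca$scores))
  assay_ids <- rownames(Y) %||% paste0("assay_", seq_len(nrow(Y)))

  rle <- if (is.null(counts)) rle_stats(Y, log = FALSE) else rle_stats(counts)

  r2 <- purrr::imap(covariates, function(v, nm) {
    tibble::tibble(variable = nm, k = seq_len(k_max),
                   r2 = as.numeric(r2_cumulative_pcs(pca, v, k_max)))
  }) |> dplyr::bind_rows()

  vc <- purrr::imap(factors, function(f, nm) {
    tibble::tibble(variable = nm, k = seq_len(k_max),
                   vector_correlation = vapply(seq_len(k_max), function(k) {
                     vector_correlation(pca$scores[, seq_len(k), drop = FALSE], f)
                   }, numeric(1)))
  }) |> dplyr::bind_rows()

  cl <- purrr::imap(factors, function(f, nm) {
    tibble::tibble(variable = nm,
                   silhouette_mean = silhouette_mean(pca, f),
                   ari = ari_by_label(pca, f, seed = seed))
  }) |> dplyr::bind_rows()

  ga <- dplyr::bind_rows(
    purrr::imap(covariates, function(v, nm) {
      tibble::tibble(variable = nm, gene_id = colnames(Y) %||%
                       paste0("gene_", seq_len(ncol(Y))),
                     statistic = "spearman",
                     value = as.numeric(spearman_per_gene(Y, v)))
    }),
    purrr::imap(factors, function(f, nm) {
      tibble::tibble(variable = nm, gene_id = colnames(Y) %||%
                       paste0("gene_", seq_len(ncol(Y))),
                     statistic = "anova_f",
                     value = as.numeric(anova_f_per_gene(Y, f)))
    }))

  de <- purrr::imap(de_groups, function(g, nm) {
    res <- de_pvalues(Y, g)
    tibble::tibble(comparison = nm, fraction_sig = res$fraction_sig)
  }) |> dplyr::bind_rows()

  sc <- purrr::imap(genesets, function(gs, nm) {
    tibble::tibble(signature = nm, assay_id = assay_ids,
                   score = as.numeric(signature_score(Y, gs)))
  }) |> dplyr::bind_rows()

  structure(list(rle_per_assay = rle,
                 pc_variance = tibble::tibble(
                   component = seq_along(pca$var_explained),
                   var_explained = pca$var_explained),
                 r2_by_cumulative_pc = r2,
                 vector_correlation_by_cumulative_pc = vc,
                 cluster_metrics = cl,
                 gene_assoc = ga,
                 de_fractions = de,
                 score_per_assay = sc,
                 pca = pca),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Unwanted-variation assessment report\n")
  for (nm in setdiff(names(x), "pca")) {
    tab <- x[[nm]]
    cat("  $", nm, ": ", nrow(tab), " rows\n", sep = "")
  }
  invisible(x)
}
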