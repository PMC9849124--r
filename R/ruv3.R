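#' Build the assay-to-sample mapping matrix
#'
#' Encodes a replicate structure as the binary matrix M (m assays x m1 distinct
#' samples) with `M[i, h] = 1` exactly when assay i is a replicate of sample h.
#' Each row sums to 1 and the column sums are the replicate counts, so
#' `t(M) %*% M` is diagonal. Columns are ordered by first appearance of each
#' sample label.
#'
#' @param replicates Character or factor vector of sample labels, one per
#'   assay. Assays sharing a label are (pseudo-)replicates of one sample.
#' @return Binary matrix with `length(replicates)` rows, one column per
#'   distinct label, column names the labels.
#' @export
build_mapping_matrix <- function(replicates) {
  if (length(replicates) == 0L) stop("`replicates` is empty")
  if (anyNA(replicates)) stop("`replicates` contains missing labels")
  labels <- as.character(replicates)
  samples <- unique(labels) # first-appearance order
  M <- matrix(0L, nrow = length(labels), ncol = length(samples),
              dimnames = list(names(replicates), samples))
  M[cbind(seq_along(labels), match(labels, samples))] <- 1L
  M
}

#' Replicate-average projection P_M Y
#'
#' Replaces every entry by the mean of that gene's values over all assays that
#' are replicates of the same sample. This is the orthogonal projection
#' `P_M = M (t(M) M)^-1 t(M)` applied to Y, computed by group averaging.
#'
#' @param Y Numeric matrix, assays x genes.
#' @param replicates Sample label per assay (see [build_mapping_matrix()]).
#' @return Matrix of the same shape as `Y`.
#' @export
replicate_average <- function(Y, replicates) {
  Y <- as.matrix(Y)
  if (nrow(Y) != length(replicates)) {
    stop("`replicates` must have one label per row of `Y`")
  }
  f <- factor(as.character(replicates), levels = unique(as.character(replicates)))
  means <- rowsum(Y, f, reorder = FALSE) / as.vector(table(f))
  out <- means[as.integer(f), , drop = FALSE]
  dimnames(out) <- dimnames(Y)
  out
}

#' Replicate residuals R_M Y
#'
#' The residual projector `R_M = I - P_M` applied to Y: each value minus its
#' replicate-set mean. Within every replicate set each gene's residuals sum to
#' zero; the residual matrix carries only the variation *between* replicates
#' of the same sample, which for (pseudo-)replicates is unwanted variation.
#'
#' @inheritParams replicate_average
#' @return Matrix of the same shape as `Y`.
#' @export
replicate_residual <- function(Y, replicates) {
  as.matrix(Y) - replicate_average(Y, replicates)
}

#' Fit RUV-III
#'
#' Estimates and removes `k` dimensions of unwanted variation from a log-scale
#' expression matrix using replicate structure and negative control genes.
#' Writing `R_M` for the replicate residual projector, the three steps are:
#' (I) take the first `k` left singular vectors `U_k` of `R_M Y` and set
#' `alpha_hat = t(U_k) Y`; (II) regress the column-centered controls
#' `(I - P_1) Y_c` on `alpha_hat_c` to obtain
#' `W_hat = (I - P_1) Y_c t(a_c) [a_c t(a_c)]^-1` with `a_c = t(U_k) Y_c`
#' (the bracketed inverse is a Moore-Penrose pseudo-inverse); (III) form the
#' adjusted matrix `Y - W_hat alpha_hat`. Gene means are never subtracted:
#' only the estimated unwanted component is removed.
#'
#' When the replicate map contains PRPS rows, the fit uses all rows and
#' `return_subset` restricts the adjusted matrix to the real assays afterwards.
#'
#' @inheritParams replicate_average
#' @param controls Negative control genes: character ids, logical mask or
#'   column indices. Assumed unaffected by the biology of interest.
#' @param k Integer dimension of unwanted variation, `0 <= k <= m - m1` where
#'   `m1` is the number of distinct sample labels. `k = 0` is the identity
#'   fit (nothing removed).
#' @param return_subset Optional assay ids (or row indices) to keep in the
#'   adjusted matrix, typically the real (non-PRPS) assays.
#' @param method Factorization path: `"svd"` (default, SVD of `R_M Y`) or
#'   `"eigen"` (eigendecomposition of `R_M Y t(Y) R_M`); both give the same
#'   fit and the second is retained as a cross-check.
#' @param pinv_rtol Relative singular-value cutoff for the pseudo-inverse.
#' @return A `ruv_fit` object: list with `adjusted` (assays x genes matrix),
#'   `W` (m x k scores of unwanted factors, columns mean-centered), `alpha`
#'   (k x n loadings), `spectrum` (non-increasing singular values of
#'   `R_M Y`), `k`, `m`, `m1`, `n`, `controls` (resolved gene indices) and
#'   `method`.
#' @export
ruv3_fit <- function(Y, replicates, controls, k,
                     return_subset = NULL,
                     method = c("svd", "eigen"),
                     pinv_rtol = 1e-12) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  validate_expression(Y)
  m <- nrow(Y); n <- ncol(Y)
  if (length(replicates) != m) stop("`replicates` must have one label per assay")
  m1 <- length(unique(as.character(replicates)))
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be non-negative")
  if (k >= 1L && m1 == m) {
    stop("no replicated samples: R_M Y = 0, nothing to estimate for k >= 1")
  }
  if (k > m - m1) {
    stop("k = ", k, " exceeds m - m1 = ", m - m1,
         " (more unwanted dimensions than replicate residual degrees of freedom)")
  }

  keep <- resolve_return_subset(Y, return_subset)

  if (k == 0L) {
    fit <- new_ruv_fit(
      adjusted = Y[keep, , drop = FALSE],
      W = matrix(numeric(0), m, 0, dimnames = list(rownames(Y), NULL)),
      alpha = matrix(numeric(0), 0, n, dimnames = list(NULL, colnames(Y))),
      spectrum = numeric(0), k = 0L, m = m, m1 = m1, n = n,
      controls = resolve_controls(Y, controls), method = method)
    return(fit)
  }

  ctl <- resolve_controls(Y, controls)

  RY <- replicate_residual(Y, replicates)
  if (max(abs(RY)) < 1e-12) {
    stop("replicate residuals are identically zero (all replicates equal); ",
         "the spectrum of R_M Y is zero and no unwanted variation can be estimated")
  }

  if (method == "svd") {
    s <- svd(RY)
    spectrum <- s$d
    U_k <- s$u[, seq_len(k), drop = FALSE]
  } else {
    E <- eigen(tcrossprod(RY), symmetric = TRUE)
    spectrum <- sqrt(pmax(E$values, 0))
    U_k <- E$vectors[, seq_len(k), drop = FALSE]
  }

  alpha <- crossprod(U_k, Y)                       # k x n
  a_c <- alpha[, ctl, drop = FALSE]                # k x n_c
  Yc0 <- scale(Y[, ctl, drop = FALSE], center = TRUE, scale = FALSE) # (I - P1) Y_c
  W <- Yc0 %*% t(a_c) %*% pinv(tcrossprod(a_c), rtol = pinv_rtol)    # m x k
  adjusted <- Y - W %*% alpha

  dimnames(W) <- list(rownames(Y), paste0("W", seq_len(k)))
  dimnames(alpha) <- list(paste0("W", seq_len(k)), colnames(Y))

  new_ruv_fit(adjusted = adjusted[keep, , drop = FALSE],
              W = W, alpha = alpha, spectrum = spectrum,
              k = k, m = m, m1 = m1, n = n, controls = ctl, method = method)
}

resolve_return_subset <- function(Y, return_subset) {
  if (is.null(return_subset)) return(seq_len(nrow(Y)))
  if (is.character(return_subset)) {
    if (is.null(rownames(Y))) stop("Y has no assay names; pass `return_subset` as indices")
    idx <- match(return_subset, rownames(Y))
    if (anyNA(idx)) stop("`return_subset` names absent from Y")
    idx
  } else {
    idx <- as.integer(return_subset)
    if (any(idx < 1L | idx > nrow(Y))) stop("`return_subset` index out of range")
    idx
  }
}

new_ruv_fit <- function(adjusted, W, alpha, spectrum, k, m, m1, n, controls, method) {
  structure(list(adjusted = adjusted, W = W, alpha = alpha, spectrum = spectrum,
                 k = k, m = m, m1 = m1, n = n, controls = controls,
                 method = method),
            class = "ruv_fit")
}

#' @export
print.ruv_fit <- function(x, ...) {
  cat("RUV-III fit\n")
  cat("  assays (m):", x$m, " distinct samples (m1):", x$m1,
      " genes (n):", x$n, "\n")
  cat("  unwanted dimension k:", x$k, " controls:", length(x$controls), "\n")
  if (length(x$spectrum)) {
    cat("  leading singular values of R_M Y:",
        paste(signif(utils::head(x$spectrum, 5), 4), collapse = ", "), "\n")
  }
  cat("  adjusted matrix:", nrow(x$adjusted), "x", ncol(x$adjusted), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the estimated unwanted factors of a RUV-III fit
#'
#' @param x A `ruv_fit`.
#' @param ... Unused.
#' @return Tibble with one row per assay and factor: `assay_id`, `factor`,
#'   `score` (the entries of `W_hat`).
#' @export
tidy.ruv_fit <- function(x, ...) {
  if (x$k == 0L) {
    return(tibble::tibble(assay_id = character(), factor = character(),
                          score = numeric()))
  }
  W <- x$W
  if (is.null(rownames(W))) rownames(W) <- paste0("assay_", seq_len(nrow(W)))
  tibble::as_tibble(W, rownames = "assay_id") |>
    tidyr::pivot_longer(-"assay_id", names_to = "factor", values_to = "score")
}

#' One-row summary of a RUV-III fit
#'
#' @param x A `ruv_fit`.
#' @param ... Unused.
#' @return Tibble with `m`, `m1`, `n`, `k`, `n_controls` and the leading
#'   singular value of the replicate residual matrix.
#' @export
glance.ruv_fit <- function(x, ...) {
  tibble::tibble(m = x$m, m1 = x$m1, n = x$n, k = x$k,
                 n_controls = length(x$controls),
                 sigma1 = if (length(x$spectrum)) x$spectrum[1] else NA_real_)
}

#' Refit RUV-III over a range of k and score each fit
#'
#' There is no closed-form rule for the unwanted dimension; practice is to
#' refit for a range of `k` and inspect diagnostics. Each fit is scored with
#' the supplied metric functions evaluated on the adjusted matrix, plus the
#' Frobenius norm of the control-gene replicate residuals (which can never
#' increase with `k`).
#'
#' @inheritParams ruv3_fit
#' @param k_values Integer vector of candidate dimensions.
#' @param metrics Named list of functions, each taking the adjusted matrix
#'   (real assays only if `return_subset` is given) and returning one number.
#' @return Tibble with one row per k: `k`, `ctl_residual_fnorm`, one column
#'   per metric, and `error` (NA on success; out-of-range k are reported here
#'   rather than raised).
#' @export
sweep_k <- function(Y, replicates, controls, k_values, metrics = list(),
                    return_subset = NULL, method = "svd") {
  stopifnot(is.list(metrics))
  rows <- purrr::map(k_values, function(k) {
    res <- tryCatch(
      ruv3_fit(Y, replicates, controls, k = k,
               return_subset = return_subset, method = method),
      error = function(e) e)
    if (inherits(res, "error")) {
      vals <- stats::setNames(rep(NA_real_, length(metrics)), names(metrics))
      return(tibble::tibble(k = as.integer(k), ctl_residual_fnorm = NA_real_,
                            !!!vals, error = conditionMessage(res)))
    }
    full_adj <- Y - if (res$k > 0) res$W %*% res$alpha else 0
    ctl_res <- replicate_residual(full_adj[, res$controls, drop = FALSE], replicates)
    vals <- purrr::map_dbl(metrics, function(f) f(res$adjusted))
    tibble::tibble(k = as.integer(k),
                   ctl_residual_fnorm = sqrt(sum(ctl_res^2)),
                   !!!vals, error = NA_character_)
  })
  dplyr::bind_rows(rows)
}
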