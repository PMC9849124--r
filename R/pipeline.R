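#' One-call RUV-III normalization with PRPS
#'
#' Convenience wrapper tying the workflow together: log-transform the counts,
#' build batch PRPS (and optionally library-size and purity PRPS), select
#' negative control genes if none are given, augment the matrix, fit RUV-III
#' and return the adjusted matrix restricted to the real assays.
#'
#' @param counts Raw count matrix, assays x genes (filter first; see
#'   [filter_genes()] and [filter_assays()]).
#' @param meta Metadata tibble with `assay_id` plus the referenced columns.
#' @param k Unwanted-variation dimension passed to [ruv3_fit()].
#' @param biology,batch Metadata columns of the biology and batch labels.
#' @param ls Metadata column of log2 library size, or NULL to skip
#'   library-size PRPS.
#' @param purity Metadata column of tumor purity, or NULL to skip purity
#'   PRPS.
#' @param controls Control gene ids; default: the `n_controls` genes with
#'   lowest one-way ANOVA F against `biology`.
#' @param n_controls Size of the default control set.
#' @param min_per_batch,min_batches Batch PRPS thresholds (see
#'   [make_batch_prps()]).
#' @param n_extreme,ls_min_group Continuous PRPS parameters for library
#'   size.
#' @param purity_within Optional column to stratify purity pairs by
#'   (default: the batch column; set NULL for one pair per biology group).
#' @param pseudocount Log-transform offset.
#' @return List with `adjusted` (real assays x genes, log2 scale), `fit`
#'   (the `ruv_fit`), `Y` (the log2 input), `controls`, and `prps` (the list
#'   of `prps_set`s used).
#' @export
ruv_normalize <- function(counts, meta, k,
                          biology = "biology", batch = "plate",
                          ls = "log2_library_size", purity = NULL,
                          controls = NULL, n_controls = 500L,
                          min_per_batch = 3L, min_batches = 2L,
                          n_extreme = 3L, ls_min_group = 12L,
                          purity_within = batch,
                          pseudocount = 1) {
  Y <- log_counts(counts, pseudocount)
  meta <- tibble::as_tibble(meta)
  if (is.null(controls)) {
    controls <- as.character(select_ncg(Y, gene_criterion(
      "low_biology_F", "anova_f", meta[[biology]][match(rownames(Y), meta$assay_id)],
      "keep_low", rank_count = n_controls)))
  }
  prps <- list(make_batch_prps(Y, meta, biology, batch,
                               min_per_batch = min_per_batch,
                               min_batches = min_batches))
  if (!is.null(ls)) {
    prps <- c(prps, list(make_continuous_prps(
      Y, meta, biology, ls, n_extreme = n_extreme,
      min_group = max(2L * n_extreme, ls_min_group), prefix = "ls")))
  }
  if (!is.null(purity)) {
    prps <- c(prps, list(make_continuous_prps(
      Y, meta, biology, purity, n_extreme = n_extreme,
      min_group = 2L * n_extreme, within = purity_within, prefix = "purity")))
  }
  aug <- augment_with_prps(Y, prps)
  fit <- ruv3_fit(aug$Y, aug$replicates, controls, k = k,
                  return_subset = which(aug$is_real))
  list(adjusted = fit$adjusted, fit = fit, Y = Y,
       controls = controls, prps = prps)
}

#' Randomly shuffle a fraction of labels
#'
#' Emulates poorly chosen PRPS: a fraction of the biology labels is permuted
#' among a random subset of assays before PRPS construction, degrading the
#' homogeneity of the pseudo-replicate sets.
#'
#' @param labels Character/factor vector.
#' @param frac Fraction of positions to permute, in \[0, 1\].
#' @param seed Integer seed.
#' @return Vector of the same length with `frac` of positions permuted.
#' @export
shuffle_labels <- function(labels, frac, seed) {
  stopifnot(frac >= 0, frac <= 1)
  with_seed(seed, {
    n <- length(labels)
    idx <- sample.int(n, round(frac * n))
    out <- labels
    out[idx] <- labels[sample(idx)]
    out
  })
}
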