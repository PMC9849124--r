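#' Benchmark RUV-III with PRPS on a library-size/plate fixture
#'
#' Runs the full recovery loop on a simulated cohort with time-structured
#' library sizes and plates nested in time (see
#' `make_fixture("readlike")`): group-aware gene filtering, lowest-F control
#' selection, batch PRPS (plates with at least two assays per biology group)
#' plus high/low library-size PRPS, and a RUV-III fit at the fixture's
#' structural dimension. Reports the gene-level library-size association, the
#' plate vector correlation and the subtype clustering agreement before and
#' after adjustment.
#'
#' @param sim A `ruv_sim` from [make_fixture()] / [simulate_counts()] with
#'   `biology`, `plate`, `time` metadata.
#' @param k Unwanted dimension (default: the structural `k_true`).
#' @param shuffle_frac Fraction of biology labels shuffled before PRPS (the
#'   poorly-chosen-PRPS experiment); control selection uses the original
#'   labels, matching the published protocol.
#' @param shuffle_seed Seed for the shuffle.
#' @param seed Seed for the clustering step.
#' @return One-row tibble: mean absolute gene-library-size Spearman
#'   correlation raw/adjusted, plate vector correlation (first 5 PCs)
#'   raw/adjusted, subtype ARI raw/adjusted.
#' @export
benchmark_library_size_removal <- function(sim, k = sim$truth$k_true,
                                           shuffle_frac = 0,
                                           shuffle_seed = 1L, seed = 11L) {
  meta <- sim$meta
  filt <- filter_genes(sim$counts,
                       groups = interaction(meta$biology, meta$time))
  Y <- log_counts(filt$counts)
  ls <- meta$log2_library_size
  biology <- meta$biology
  if (shuffle_frac > 0) {
    biology <- shuffle_labels(biology, shuffle_frac, seed = shuffle_seed)
  }
  meta_prps <- meta
  meta_prps$biology <- biology

  controls <- as.character(select_ncg(Y, gene_criterion(
    "low_biology_F", "anova_f", meta$biology, "keep_low", rank_count = 500L)))
  prps <- list(
    make_batch_prps(Y, meta_prps, "biology", "plate", min_per_batch = 2L),
    make_continuous_prps(Y, meta_prps, "biology", "log2_library_size",
                         n_extreme = 3L, min_group = 12L, prefix = "ls"))
  aug <- augment_with_prps(Y, prps)
  fit <- ruv3_fit(aug$Y, aug$replicates, controls, k = k,
                  return_subset = which(aug$is_real))

  pca_raw <- pca_scores(Y, 10L)
  pca_adj <- pca_scores(fit$adjusted, 10L)
  tibble::tibble(
    rho_ls_raw = mean(abs(spearman_per_gene(Y, ls))),
    rho_ls_adj = mean(abs(spearman_per_gene(fit$adjusted, ls))),
    vc_plate_raw = vector_correlation(pca_raw$scores[, 1:5], meta$plate),
    vc_plate_adj = vector_correlation(pca_adj$scores[, 1:5], meta$plate),
    ari_raw = ari_by_label(pca_raw, meta$biology, seed = seed),
    ari_adj = ari_by_label(pca_adj, meta$biology, seed = seed))
}

#' Benchmark tumor-purity removal and retention on a purity fixture
#'
#' Runs the purity workflow on a simulated cohort with a tumor/stroma purity
#' mixture, two flow-cell chemistries and plates (see
#' `make_fixture("brcalike")`). With `with_purity_prps = TRUE` the PRPS
#' include high/low-purity pairs within each biology-by-plate cell and the
#' fit uses the full structural dimension; with `FALSE` purity is left
#' untargeted (one dimension less), testing that untargeted variation is
#' retained.
#'
#' @inheritParams benchmark_library_size_removal
#' @param with_purity_prps Include purity PRPS (and the purity dimension)?
#' @return One-row tibble: purity R-squared on the cumulative first 5 PCs
#'   raw/adjusted, chemistry vector correlation raw/adjusted, subtype ARI
#'   raw/adjusted, and `k` used.
#' @export
benchmark_purity_removal <- function(sim, with_purity_prps = TRUE,
                                     k = NULL, seed = 11L) {
  meta <- sim$meta
  filt <- filter_genes(sim$counts, groups = meta$biology)
  Y <- log_counts(filt$counts)
  k <- k %||% (sim$truth$k_true - (!with_purity_prps))

  controls <- as.character(select_ncg(Y, gene_criterion(
    "low_biology_F", "anova_f", meta$biology, "keep_low", rank_count = 500L)))
  prps <- list(
    make_batch_prps(Y, meta, "biology", "plate"),
    make_continuous_prps(Y, meta, "biology", "log2_library_size",
                         n_extreme = 3L, min_group = 12L, prefix = "ls"))
  if (with_purity_prps) {
    prps <- c(prps, list(make_continuous_prps(
      Y, meta, "biology", "purity", n_extreme = 3L, min_group = 6L,
      within = "plate", prefix = "purity")))
  }
  aug <- augment_with_prps(Y, prps)
  fit <- ruv3_fit(aug$Y, aug$replicates, controls, k = k,
                  return_subset = which(aug$is_real))

  pca_raw <- pca_scores(Y, 10L)
  pca_adj <- pca_scores(fit$adjusted, 10L)
  tibble::tibble(
    purity_r2_raw = r2_cumulative_pcs(pca_raw, meta$purity, 5L)[[5]],
    purity_r2_adj = r2_cumulative_pcs(pca_adj, meta$purity, 5L)[[5]],
    vc_chemistry_raw = vector_correlation(pca_raw$scores[, 1:5], meta$chemistry),
    vc_chemistry_adj = vector_correlation(pca_adj$scores[, 1:5], meta$chemistry),
    ari_raw = ari_by_label(pca_raw, meta$biology, seed = seed),
    ari_adj = ari_by_label(pca_adj, meta$biology, seed = seed),
    k = k)
}
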