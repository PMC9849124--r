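#' RLE box plot
#'
#' One box of relative log expression per assay, ordered as supplied (use a
#' processing-date order to reveal temporal drift). Medians far from zero, or
#' uneven IQRs, indicate unwanted variation.
#'
#' @param x Matrix accepted by [rle_stats()], or its output.
#' @param color_by Optional per-assay vector used to color the boxes.
#' @param ... Passed to [rle_stats()] when `x` is a matrix.
#' @return A ggplot object.
#' @export
plot_rle <- function(x, color_by = NULL, ...) {
  stats_tbl <- if (is.matrix(x)) rle_stats(x, ...) else x
  rle <- attr(stats_tbl, "rle")
  if (is.null(rle)) stop("no RLE matrix attached; pass the matrix itself")
  df <- tibble::as_tibble(rle, rownames = "assay_id") |>
    tidyr::pivot_longer(-"assay_id", names_to = "gene_id", values_to = "rle")
  df$assay_id <- factor(df$assay_id, levels = stats_tbl$assay_id)
  if (!is.null(color_by)) df$color <- rep(color_by, each = ncol(rle))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$assay_id, y = .data$rle))
  p <- if (is.null(color_by)) p + ggplot2::geom_boxplot(outlier.size = 0.3)
  else p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data$color),
                                 outlier.size = 0.3)
  p + ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "relative log expression", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Principal-component scatter plot
#'
#' @param scores A `pca_scores` object (see [pca_scores()]).
#' @param color_by Optional per-assay vector (factor or numeric) to color
#'   points: a batch, subtype, library size, purity, ...
#' @param dims Which two components to plot (default 1 and 2).
#' @return A ggplot object.
#' @export
plot_pca <- function(scores, color_by = NULL, dims = c(1L, 2L)) {
  S <- get_scores(scores)
  ve <- if (inherits(scores, "pca_scores")) scores$var_explained else NULL
  df <- tibble::tibble(x = S[, dims[1]], y = S[, dims[2]])
  if (!is.null(color_by)) df$color <- color_by
  lab <- function(d) {
    if (is.null(ve)) paste0("PC", d) else
      sprintf("PC%d (%.1f%%)", d, 100 * ve[d])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (is.null(color_by)) p + ggplot2::geom_point(size = 1)
  else p + ggplot2::geom_point(ggplot2::aes(color = .data$color), size = 1)
  p + ggplot2::labs(x = lab(dims[1]), y = lab(dims[2]), color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scree plot of the replicate-residual spectrum of a RUV-III fit
#'
#' The singular values of `R_M Y`: a sharp elbow suggests how many unwanted
#' dimensions the replicate structure exposes.
#'
#' @param object A `ruv_fit`.
#' @param n_values How many leading singular values to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ruv_fit <- function(object, n_values = 20L, ...) {
  s <- utils::head(object$spectrum, n_values)
  df <- tibble::tibble(index = seq_along(s), sigma = s)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$sigma)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$k + 0.5, linetype = 2) +
    ggplot2::labs(x = "component",
                  y = "singular value of replicate residuals") +
    ggplot2::theme_minimal()
}
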