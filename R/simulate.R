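#' Configure a synthetic bulk RNA-seq dataset
#'
#' Builds the configuration for [simulate_counts()]. The generator realizes
#' the unwanted-variation structure seen in large tumor compendia: a
#' gene-specific response to library size (four classes: proportional,
#' super-proportional, independent, inverse), tumor purity acting as a
#' count-scale tumor/stroma mixture, additive per-gene plate (batch) effects
#' on the log scale, subtype-specific biological signal, and
#' negative-binomial counting noise.
#'
#' The per-gene, per-assay log2 mean is
#' `mu_g + x_i' beta_g + gamma_g (l_i - mean(l)) + delta_{plate(i), g}`,
#' with `mu_g` replaced by the purity mixture
#' `log2(p_i 2^mu_g + (1 - p_i) 2^{s_g})` when purity is enabled (mixing is
#' linear on the count scale, matching the physical mixing of tumor and
#' stromal tissue in a bulk sample). Counts are drawn negative-binomial with
#' variance `mu + dispersion * mu^2`.
#'
#' @param m,n Number of assays and genes.
#' @param seed Integer seed (mandatory; identical seed, identical dataset).
#' @param n_subtypes Number of biological subtypes.
#' @param subtype_props Subtype proportions (default equal; must sum to 1).
#' @param beta_sd SD of the per-subtype log2 effect for non-null genes.
#' @param frac_null Fraction of genes with beta = 0 (unaffected by biology;
#'   the control-eligible pool). Default 0.5.
#' @param n_times Number of processing-time strata (default 1).
#' @param time_props Proportions of assays per time stratum.
#' @param n_plates Total plates; plates are divided among time strata
#'   (nesting plates in time, the usual confounding).
#' @param plate_scheme How assays are assigned to their stratum's plates:
#'   `"balanced"` (default) distributes each subtype round-robin across the
#'   plates of its time stratum, emulating studies where biology is
#'   well-distributed over batches; `"random"` assigns uniformly, allowing
#'   composition imbalance (partial biology-batch confounding).
#' @param plate_sd SD of the additive per-gene, per-plate log2 effect.
#' @param chemistry_of_plate Optional vector (length `n_plates`) of chemistry
#'   labels; plates sharing a label share an extra per-gene offset with SD
#'   `chemistry_sd` (flow-cell-chemistry style variation nested in plates).
#' @param chemistry_sd SD of the per-gene chemistry offset.
#' @param ls_meanlog2,ls_sdlog2 Mean and SD of the generative log2 library
#'   size within a time stratum (log-normal library sizes).
#' @param ls_shift Per-time-stratum additive shift of log2 library size
#'   (length `n_times`; large values mimic the year-to-year shifts of real
#'   compendia).
#' @param class_props Mixture over the four library-size response classes
#'   (proportional, super-proportional, independent, inverse); must sum to 1.
#' @param class_gamma The class coefficients gamma on the log2 scale
#'   (default 1, 1.5, 0, -0.5).
#' @param purity NULL (off) or a list with `shape1`, `shape2` (Beta
#'   parameters of purity), `divergence` (log2 magnitude of the
#'   stromal-vs-tumor expression difference of affected genes, applied with
#'   random sign — stromal-specific genes up, tumor-specific genes down) and
#'   `frac_affected` (fraction of genes with a distinct stromal profile).
#' @param mu_mean,mu_sd Mean/SD of the baseline log2 gene means.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi mu^2`); 0 gives Poisson.
#' @param counting Draw counting noise? `FALSE` returns the deterministic
#'   means (rounded off nowhere): useful for exactness checks.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m, n, seed,
                       n_subtypes = 2L, subtype_props = NULL,
                       beta_sd = 1, frac_null = 0.5,
                       n_times = 1L, time_props = NULL,
                       n_plates = 2L, plate_scheme = c("balanced", "random"),
                       plate_sd = 0.5,
                       chemistry_of_plate = NULL, chemistry_sd = 1,
                       ls_meanlog2 = 25, ls_sdlog2 = 0.5,
                       ls_shift = rep(0, n_times),
                       class_props = c(proportional = 0.5,
                                       super_proportional = 0.2,
                                       independent = 0.2,
                                       inverse = 0.1),
                       class_gamma = c(proportional = 1,
                                       super_proportional = 1.5,
                                       independent = 0,
                                       inverse = -0.5),
                       purity = NULL,
                       mu_mean = 8, mu_sd = 2,
                       dispersion = 0.1, counting = TRUE) {
  if (missing(seed)) stop("`seed` is mandatory")
  plate_scheme <- match.arg(plate_scheme)
  subtype_props <- subtype_props %||% rep(1 / n_subtypes, n_subtypes)
  time_props <- time_props %||% rep(1 / n_times, n_times)
  stopifnot(m >= 2, n >= 1, n_subtypes >= 1, n_plates >= 1,
            length(subtype_props) == n_subtypes,
            length(time_props) == n_times,
            length(ls_shift) == n_times,
            abs(sum(subtype_props) - 1) < 1e-8,
            abs(sum(time_props) - 1) < 1e-8,
            abs(sum(class_props) - 1) < 1e-8,
            length(class_props) == 4L, length(class_gamma) == 4L,
            plate_sd >= 0, beta_sd >= 0, ls_sdlog2 >= 0, dispersion >= 0,
            frac_null >= 0, frac_null <= 1,
            m >= n_plates, n_plates >= n_times)
  cls <- c("proportional", "super_proportional", "independent", "inverse")
  class_props <- stats::setNames(as.numeric(class_props), cls)
  class_gamma <- stats::setNames(as.numeric(class_gamma), cls)
  if (!is.null(chemistry_of_plate)) {
    stopifnot(length(chemistry_of_plate) == n_plates)
  }
  if (!is.null(purity)) {
    stopifnot(is.list(purity),
              all(c("shape1", "shape2", "divergence", "frac_affected")
                  %in% names(purity)))
  }
  structure(list(m = as.integer(m), n = as.integer(n), seed = as.integer(seed),
                 n_subtypes = as.integer(n_subtypes), subtype_props = subtype_props,
                 beta_sd = beta_sd, frac_null = frac_null,
                 n_times = as.integer(n_times), time_props = time_props,
                 n_plates = as.integer(n_plates), plate_scheme = plate_scheme,
                 plate_sd = plate_sd,
                 chemistry_of_plate = chemistry_of_plate,
                 chemistry_sd = chemistry_sd,
                 ls_meanlog2 = ls_meanlog2, ls_sdlog2 = ls_sdlog2,
                 ls_shift = ls_shift,
                 class_props = class_props, class_gamma = class_gamma,
                 purity = purity, mu_mean = mu_mean, mu_sd = mu_sd,
                 dispersion = dispersion, counting = isTRUE(counting)),
            class = "sim_config")
}

#' Simulate a bulk RNA-seq count matrix with known unwanted variation
#'
#' Draws a dataset from a [sim_config()] generative model and returns the raw
#' counts together with sample metadata and the complete ground truth, so
#' that every downstream operation (PRPS, control selection, RUV-III,
#' diagnostics) can be tested against known parameters.
#'
#' @param config A `sim_config`.
#' @return A `ruv_sim` list: `counts` (m x n integer-valued matrix, assays x
#'   genes), `meta` (tibble: `assay_id`, `biology`, `plate`, `time`,
#'   `chemistry`, `log2_library_size` — the emergent log2 total count — and
#'   `purity`), and `truth` (list: design `X`, `beta`, `mu`, per-gene `gamma`
#'   and `class`, plate effects `delta`, stromal profile `s_g`, generative
#'   log2 library size `ls_gen`, `purity`, the per-cell `log2_mean`, and
#'   `k_true`, the structural dimension of the injected unwanted variation).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  c0 <- config
  with_seed(c0$seed, {
    m <- c0$m; n <- c0$n
    assay_id <- sprintf("assay_%03d", seq_len(m))
    gene_id <- sprintf("gene_%04d", seq_len(n))

    subtype <- sample(paste0("subtype", seq_len(c0$n_subtypes)), m,
                      replace = TRUE, prob = c0$subtype_props)
    # guarantee every subtype appears at least twice so ANOVA/PRPS are defined
    for (s in paste0("subtype", seq_len(c0$n_subtypes))) {
      while (sum(subtype == s) < 2L) subtype[sample.int(m, 1)] <- s
    }
    time <- sample(paste0("time", seq_len(c0$n_times)), m,
                   replace = TRUE, prob = c0$time_props)
    # plates nested in time: divide plates among strata, round-robin
    plate_time <- rep(seq_len(c0$n_times), length.out = c0$n_plates)
    time_idx <- match(time, paste0("time", seq_len(c0$n_times)))
    plate <- character(m)
    if (c0$plate_scheme == "random") {
      for (i in seq_len(m)) {
        pool <- which(plate_time == time_idx[i])
        plate[i] <- sprintf("plate%02d", pool[sample.int(length(pool), 1)])
      }
    } else {
      # balanced: within each (time, subtype) cell deal assays round-robin
      # across the stratum's plates, so plate compositions match
      for (tt in seq_len(c0$n_times)) {
        pool <- which(plate_time == tt)
        for (s in unique(subtype)) {
          cell <- which(time_idx == tt & subtype == s)
          if (length(cell)) {
            plate[cell] <- sprintf("plate%02d",
                                   pool[1L + (sample(seq_along(cell)) - 1L) %% length(pool)])
          }
        }
      }
    }
    plate_idx <- as.integer(sub("plate", "", plate))
    chemistry <- if (is.null(c0$chemistry_of_plate)) rep("chemA", m) else
      as.character(c0$chemistry_of_plate)[plate_idx]

    ls_gen <- c0$ls_meanlog2 +
      c0$ls_shift[match(time, paste0("time", seq_len(c0$n_times)))] +
      stats::rnorm(m, 0, c0$ls_sdlog2)

    mu <- stats::rnorm(n, c0$mu_mean, c0$mu_sd)
    mu <- pmin(pmax(mu, 0), 14)
    null_gene <- seq_len(n) <= round(c0$frac_null * n) # deterministic block
    beta <- matrix(0, c0$n_subtypes, n,
                   dimnames = list(paste0("subtype", seq_len(c0$n_subtypes)), gene_id))
    if (any(!null_gene) && c0$beta_sd > 0) {
      beta[, !null_gene] <- stats::rnorm(c0$n_subtypes * sum(!null_gene),
                                         0, c0$beta_sd)
    }
    gene_class <- sample(names(c0$class_props), n, replace = TRUE,
                         prob = c0$class_props)
    gamma <- unname(c0$class_gamma[gene_class])

    delta <- matrix(stats::rnorm(c0$n_plates * n, 0, c0$plate_sd), c0$n_plates, n)
    if (!is.null(c0$chemistry_of_plate)) {
      chem_levels <- unique(c0$chemistry_of_plate)
      chem_eff <- matrix(0, length(chem_levels), n)
      if (length(chem_levels) > 1L) {
        chem_eff[-1, ] <- stats::rnorm((length(chem_levels) - 1L) * n,
                                       0, c0$chemistry_sd)
      }
      delta <- delta + chem_eff[match(c0$chemistry_of_plate, chem_levels), ]
    }

    X <- matrix(0, m, c0$n_subtypes, dimnames = list(assay_id, rownames(beta)))
    X[cbind(seq_len(m),
            match(subtype, paste0("subtype", seq_len(c0$n_subtypes))))] <- 1

    base <- matrix(mu, m, n, byrow = TRUE)
    purity_i <- rep(NA_real_, m)
    s_g <- rep(NA_real_, n)
    if (!is.null(c0$purity)) {
      purity_i <- stats::rbeta(m, c0$purity$shape1, c0$purity$shape2)
      affected <- stats::runif(n) < c0$purity$frac_affected
      s_g <- mu
      s_g[affected] <- mu[affected] +
        sample(c(-1, 1), sum(affected), replace = TRUE) * c0$purity$divergence
      base <- log2(outer(purity_i, 2^mu) + outer(1 - purity_i, 2^s_g))
    }

    log2_mean <- base + X %*% beta +
      outer(ls_gen - mean(ls_gen), gamma) +
      delta[plate_idx, , drop = FALSE]

    mu_count <- 2^log2_mean
    counts <- if (!c0$counting) {
      mu_count
    } else if (c0$dispersion == 0) {
      matrix(stats::rpois(m * n, lambda = mu_count), m, n)
    } else {
      matrix(stats::rnbinom(m * n, mu = mu_count, size = 1 / c0$dispersion), m, n)
    }
    dimnames(counts) <- list(assay_id, gene_id)

    k_true <- (c0$n_plates - 1L) +
      as.integer(any(gamma != 0) && stats::sd(ls_gen) > 0) +
      as.integer(!is.null(c0$purity))

    meta <- tibble::tibble(
      assay_id = assay_id, biology = subtype, plate = plate, time = time,
      chemistry = chemistry,
      log2_library_size = log2(rowSums(counts) + 1),
      purity = purity_i)

    truth <- list(X = X, beta = beta, mu = mu, gamma = gamma,
                  class = gene_class, null_gene = null_gene,
                  delta = delta, s_g = s_g, ls_gen = ls_gen,
                  purity = purity_i, log2_mean = log2_mean, k_true = k_true)

    structure(list(counts = counts, meta = meta, truth = truth,
                   config = c0),
              class = "ruv_sim")
  })
}

#' @export
print.ruv_sim <- function(x, ...) {
  cat("Simulated RNA-seq dataset:", nrow(x$counts), "assays x",
      ncol(x$counts), "genes\n")
  cat("  subtypes:", x$config$n_subtypes, " plates:", x$config$n_plates,
      " time strata:", x$config$n_times,
      " purity:", !is.null(x$config$purity), "\n")
  cat("  structural unwanted dimension k_true:", x$truth$k_true, "\n")
  invisible(x)
}

#' Built-in study-like fixtures
#'
#' Three deterministic datasets used throughout the tests and examples:
#' `tiny` (12 assays x 60 genes, 2 subtypes, 2 plates) for fast unit checks;
#' `readlike` (200 x 2,000; two time strata with a large library-size shift,
#' plates nested in time, 4 subtypes) emulating a rectal-cancer-sized cohort
#' where library sizes vary greatly both within and between years; and
#' `brcalike` (300 x 2,000; tumor purity as a Beta-distributed tumor/stroma
#' mixture plus a two-chemistry batch structure nested in plates) emulating a
#' breast-cancer-sized cohort.
#'
#' @param name One of `"tiny"`, `"readlike"`, `"brcalike"`.
#' @param seed Optional seed override (default: a fixed per-fixture seed, so
#'   the fixture is reproducible across sessions).
#' @param dir Optional directory; when given, the fixture is also written to
#'   disk as `counts.tsv`, `metadata.tsv` and `config.json`.
#' @return A `ruv_sim` (see [simulate_counts()]).
#' @export
make_fixture <- function(name = c("tiny", "readlike", "brcalike"),
                         seed = NULL, dir = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(m = 12L, n = 60L, seed = seed %||% 101L,
                      n_subtypes = 2L, n_plates = 2L,
                      beta_sd = 1, plate_sd = 0.5,
                      ls_sdlog2 = 0.5, dispersion = 0.1),
    readlike = sim_config(m = 200L, n = 2000L, seed = seed %||% 2020L,
                          n_subtypes = 4L,
                          n_times = 2L, time_props = c(0.25, 0.75),
                          ls_shift = c(-2, 0),
                          n_plates = 6L, plate_sd = 0.5,
                          beta_sd = 1, ls_sdlog2 = 0.5, dispersion = 0.1),
    brcalike = sim_config(m = 300L, n = 2000L, seed = seed %||% 2021L,
                          n_subtypes = 4L,
                          n_plates = 6L, plate_sd = 0.5,
                          chemistry_of_plate = rep(c("chemA", "chemB"), each = 3),
                          chemistry_sd = 0.5,
                          purity = list(shape1 = 5, shape2 = 2,
                                        divergence = 3, frac_affected = 0.5),
                          beta_sd = 1, ls_sdlog2 = 0.5, dispersion = 0.1))
  sim <- simulate_counts(cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_counts(sim$counts, file.path(dir, "counts.tsv"))
    utils::write.table(sim$meta, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(fixture = name,
           config = sim$config[setdiff(names(sim$config),
                                       c("class_props", "class_gamma"))],
           k_true = sim$truth$k_true),
      file.path(dir, "config.json"), auto_unbox = TRUE, null = "null")
  }
  sim
}
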