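#' Pseudo-replicates of pseudo-samples (PRPS)
#'
#' Large studies rarely carry technical replicates, and replicates cannot
#' expose sample-intrinsic variation such as tumor purity. PRPS works around
#' both limits: average small groups of assays that are roughly homogeneous in
#' biology *and* in an unwanted factor into pseudo-samples, then declare
#' same-biology pseudo-samples to be a pseudo-replicate set. Differences
#' between members of a set are then almost entirely unwanted variation, which
#' is exactly what the RUV-III replicate residual consumes.
#'
#' A `prps_set` holds `pseudo_values` (pseudo-samples x genes, log2 scale),
#' `pseudo_ids`, `set_label` (the pseudo-replicate set of each pseudo-sample),
#' a `provenance` tibble mapping each pseudo-sample to the assays it averages,
#' and a `recipe` descriptor.
#'
#' @name prps
NULL

new_prps_set <- function(pseudo_values, set_label, provenance, recipe) {
  structure(list(pseudo_values = pseudo_values,
                 pseudo_ids = rownames(pseudo_values),
                 set_label = set_label,
                 provenance = provenance,
                 recipe = recipe),
            class = "prps_set")
}

#' @export
print.prps_set <- function(x, ...) {
  cat("PRPS set (recipe: ", x$recipe$type, ")\n", sep = "")
  cat("  pseudo-samples:", nrow(x$pseudo_values),
      " pseudo-replicate sets:", length(unique(x$set_label)), "\n")
  if (nrow(x$pseudo_values)) {
    sizes <- table(x$set_label)
    cat("  set sizes:", paste(sizes, collapse = ", "), "\n")
  }
  invisible(x)
}

empty_prps <- function(Y, recipe, reason) {
  warning("no qualifying groups for PRPS recipe '", recipe$type, "': ", reason,
          call. = FALSE)
  new_prps_set(matrix(numeric(0), 0, ncol(Y),
                      dimnames = list(NULL, colnames(Y))),
               character(0),
               tibble::tibble(pseudo_id = character(), assay_id = character()),
               recipe)
}

check_prps_meta <- function(Y, meta, keys) {
  meta <- tibble::as_tibble(meta)
  if (!"assay_id" %in% names(meta)) stop("`meta` must have an `assay_id` column")
  missing_keys <- setdiff(keys, names(meta))
  if (length(missing_keys)) {
    stop("metadata columns not found: ", paste(missing_keys, collapse = ", "))
  }
  if (anyDuplicated(meta$assay_id)) stop("duplicated assay_id in metadata")
  if (is.null(rownames(Y))) stop("`Y` must have assay ids as rownames")
  if (!all(meta$assay_id %in% rownames(Y))) {
    stop("metadata refers to assays absent from the expression matrix")
  }
  meta
}

# Average the given assay rows of Y (log scale); fixed summation order
# (matrix column sums over rows ordered as supplied) so provenance re-averaging
# is bit-for-bit reproducible.
average_rows <- function(Y, assay_ids) {
  colSums(Y[assay_ids, , drop = FALSE]) / length(assay_ids)
}

#' Build PRPS for a categorical batch factor
#'
#' For every biology group having at least `min_per_batch` assays in at least
#' `min_batches` batches, each qualifying (biology, batch) cell is averaged
#' into one pseudo-sample, and all pseudo-samples of that biology group form
#' one pseudo-replicate set. Differences within the set are then batch (plus
#' residual) variation at constant biology.
#'
#' @param Y Log-scale expression matrix, assays x genes, assay ids as rownames.
#' @param meta Data frame with `assay_id` plus the metadata columns named by
#'   `biology` and `batch`.
#' @param biology,batch Names of the metadata columns holding the biology
#'   label (e.g. molecular subtype) and the batch label (e.g. plate).
#' @param min_per_batch Minimum assays a (biology, batch) cell needs to
#'   contribute a pseudo-sample (default 3; set 2 for sparser designs).
#' @param min_batches Minimum qualifying batches a biology group needs
#'   (default 2; a set of one pseudo-sample carries no replicate contrast and
#'   is dropped).
#' @param prefix Namespace prepended to pseudo ids and set labels so sets from
#'   different recipes never merge. Default `"batch"`.
#' @return A `prps_set` (empty, with a warning, if nothing qualifies).
#' @export
make_batch_prps <- function(Y, meta, biology, batch,
                            min_per_batch = 3L, min_batches = 2L,
                            prefix = "batch") {
  Y <- as.matrix(Y)
  meta <- check_prps_meta(Y, meta, c(biology, batch))
  recipe <- list(type = "batch", biology = biology, batch = batch,
                 min_per_batch = min_per_batch, min_batches = min_batches,
                 prefix = prefix)
  use <- meta[!is.na(meta[[biology]]) & !is.na(meta[[batch]]), ]
  if (nrow(use) == 0L) return(empty_prps(Y, recipe, "no assays with complete labels"))

  cells <- use |>
    dplyr::group_by(.bio = .data[[biology]], .batch = .data[[batch]]) |>
    dplyr::summarise(assays = list(.data$assay_id), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_per_batch)
  sets <- cells |>
    dplyr::count(.data$.bio) |>
    dplyr::filter(.data$n >= min_batches)
  cells <- dplyr::semi_join(cells, sets, by = ".bio")
  if (nrow(cells) == 0L) {
    return(empty_prps(Y, recipe, sprintf(
      "no biology group has >= %d assays in >= %d batches",
      min_per_batch, min_batches)))
  }
  cells <- dplyr::arrange(cells, .data$.bio, .data$.batch)
  pseudo_ids <- paste(prefix, cells$.bio, cells$.batch, sep = ".")
  vals <- t(vapply(cells$assays, function(a) average_rows(Y, a),
                   numeric(ncol(Y))))
  dimnames(vals) <- list(pseudo_ids, colnames(Y))
  provenance <- tibble::tibble(
    pseudo_id = rep(pseudo_ids, lengths(cells$assays)),
    assay_id = unlist(cells$assays))
  new_prps_set(vals, paste(prefix, cells$.bio, sep = "."), provenance, recipe)
}

#' Build PRPS for a continuous unwanted variable
#'
#' Within each stratum (a biology group, optionally crossed with `within`,
#' e.g. plate), the assays with the `n_extreme` highest and the `n_extreme`
#' lowest values of the continuous variable are averaged into a high and a low
#' pseudo-sample. All pseudo-samples of one biology group share a
#' pseudo-replicate set, so high-vs-low differences at constant biology expose
#' the continuous factor (library size, tumor purity, ...). Ties in the
#' continuous value are broken by a stable sort on `assay_id`.
#'
#' @inheritParams make_batch_prps
#' @param cont Name of the numeric metadata column (e.g. log2 library size or
#'   purity).
#' @param n_extreme Assays averaged into each extreme pseudo-sample
#'   (default 3).
#' @param min_group Minimum stratum size; must be at least `2 * n_extreme` so
#'   the two extremes never overlap. Default `max(2 * n_extreme, 12)`,
#'   mirroring a per-plate subtype minimum of 12 with triplets.
#' @param within Optional second stratification column (e.g. plate); strata
#'   are then (biology x within) cells and all cells of one biology still
#'   share a set.
#' @param prefix Namespace for ids and set labels. Default `cont`.
#' @return A `prps_set`.
#' @export
make_continuous_prps <- function(Y, meta, biology, cont,
                                 n_extreme = 3L,
                                 min_group = max(2L * n_extreme, 12L),
                                 within = NULL,
                                 prefix = cont) {
  Y <- as.matrix(Y)
  meta <- check_prps_meta(Y, meta, c(biology, cont, within))
  recipe <- list(type = "continuous", biology = biology, cont = cont,
                 n_extreme = n_extreme, min_group = min_group,
                 within = within, prefix = prefix)
  if (min_group < 2L * n_extreme) {
    stop("`min_group` must be at least 2 * n_extreme")
  }
  use <- meta[!is.na(meta[[biology]]) & !is.na(meta[[cont]]), ]
  if (!is.numeric(use[[cont]])) stop("`", cont, "` must be numeric")
  if (!is.null(within)) use <- use[!is.na(use[[within]]), ]
  if (nrow(use) == 0L) return(empty_prps(Y, recipe, "no assays with complete labels"))

  strata <- if (is.null(within)) {
    dplyr::group_by(use, .bio = .data[[biology]])
  } else {
    dplyr::group_by(use, .bio = .data[[biology]], .within = .data[[within]])
  }
  strata <- strata |>
    dplyr::summarise(data = list(dplyr::pick(dplyr::everything())),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= min_group)
  if (nrow(strata) == 0L) {
    return(empty_prps(Y, recipe, sprintf("no stratum has >= %d assays", min_group)))
  }
  strata <- if (is.null(within)) dplyr::arrange(strata, .data$.bio) else
    dplyr::arrange(strata, .data$.bio, .data$.within)

  rows <- purrr::pmap(strata, function(.bio, data, n, ...) {
    dots <- list(...)
    stratum_id <- if (is.null(within)) as.character(.bio) else
      paste(.bio, dots$.within, sep = ".")
    ord <- order(data[[cont]], data$assay_id) # stable tie-break by assay_id
    low <- data$assay_id[ord[seq_len(n_extreme)]]
    high <- data$assay_id[ord[seq(n - n_extreme + 1L, n)]]
    list(bio = as.character(.bio), stratum = stratum_id, low = low, high = high)
  })

  pseudo_ids <- unlist(lapply(rows, function(r) {
    paste(prefix, r$stratum, c("low", "high"), sep = ".")
  }))
  set_label <- unlist(lapply(rows, function(r) rep(paste(prefix, r$bio, sep = "."), 2L)))
  members <- unlist(lapply(rows, function(r) list(r$low, r$high)), recursive = FALSE)
  vals <- t(vapply(members, function(a) average_rows(Y, a), numeric(ncol(Y))))
  dimnames(vals) <- list(pseudo_ids, colnames(Y))
  provenance <- tibble::tibble(pseudo_id = rep(pseudo_ids, lengths(members)),
                               assay_id = unlist(members))

  # a set needs >= 2 pseudo-samples; pairs always come together, so only
  # whole-set drops below 2 are impossible here, but keep the guard uniform
  keep <- set_label %in% names(which(table(set_label) >= 2L))
  if (!all(keep)) {
    vals <- vals[keep, , drop = FALSE]
    provenance <- provenance[provenance$pseudo_id %in% rownames(vals), ]
    set_label <- set_label[keep]
  }
  new_prps_set(vals, set_label, provenance, recipe)
}

#' Stack PRPS rows onto a matrix and extend the replicate map
#'
#' Appends the pseudo-samples of one or more `prps_set`s below the real
#' assays and returns the augmented matrix together with the replicate map
#' RUV-III consumes: real assays keep their own labels (singletons unless
#' `replicates` says otherwise) and each pseudo-replicate set becomes a shared
#' label.
#'
#' @param Y Log-scale expression matrix of real assays.
#' @param prps A `prps_set` or list of them.
#' @param replicates Optional existing sample labels for the real assays
#'   (default: every real assay its own singleton sample).
#' @return List with `Y` (augmented matrix), `replicates` (labels for all
#'   rows), and `is_real` (logical mask of real assays, usable as
#'   `return_subset`).
#' @export
augment_with_prps <- function(Y, prps, replicates = NULL) {
  Y <- as.matrix(Y)
  if (inherits(prps, "prps_set")) prps <- list(prps)
  stopifnot(all(vapply(prps, inherits, logical(1), "prps_set")))
  if (is.null(replicates)) {
    replicates <- if (!is.null(rownames(Y))) rownames(Y) else
      paste0("assay_", seq_len(nrow(Y)))
  }
  replicates <- as.character(replicates)
  stopifnot(length(replicates) == nrow(Y))

  prps <- prps[vapply(prps, function(p) nrow(p$pseudo_values) > 0L, logical(1))]
  if (length(prps) == 0L) {
    return(list(Y = Y, replicates = replicates, is_real = rep(TRUE, nrow(Y))))
  }
  for (p in prps) {
    if (!identical(colnames(p$pseudo_values), colnames(Y))) {
      stop("PRPS gene order does not match the expression matrix")
    }
  }
  pv <- do.call(rbind, lapply(prps, `[[`, "pseudo_values"))
  labels <- unlist(lapply(prps, `[[`, "set_label"))
  if (anyDuplicated(rownames(pv))) stop("duplicated pseudo-sample ids across PRPS sets")
  if (any(rownames(pv) %in% rownames(Y))) stop("pseudo-sample ids collide with assay ids")
  if (any(labels %in% replicates)) stop("PRPS set labels collide with real sample labels")

  list(Y = rbind(Y, pv),
       replicates = c(replicates, labels),
       is_real = rep(c(TRUE, FALSE), c(nrow(Y), nrow(pv))))
}
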