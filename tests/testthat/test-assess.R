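test_that("RLE summaries match brute-force median subtraction", {
  set.seed(1)
  counts <- matrix(rpois(10 * 50, 100), 10, 50,
                   dimnames = list(paste0("a", 1:10), paste0("g", 1:50)))
  st <- rle_stats(counts)
  L <- log2(counts + 1)
  brute <- sweep(L, 2, apply(L, 2, median))
  expect_equal(attr(st, "rle"), brute, tolerance = 1e-12)
  expect_equal(st$median, apply(brute, 1, median), tolerance = 1e-12)
  expect_equal(st$iqr, apply(brute, 1, IQR), tolerance = 1e-12)
  # identical assays: all medians zero, all IQRs equal
  same <- matrix(rep(rpois(30, 50), each = 4), 4, 30)
  st0 <- rle_stats(same)
  expect_equal(st0$median, rep(0, 4))
  expect_equal(length(unique(round(st0$iqr, 12))), 1L)
  # shifting one assay by +c on the log scale moves its RLE median by ~ +c
  L2 <- log2(counts + 1); L2[1, ] <- L2[1, ] + 2
  st2 <- rle_stats(L2, log = FALSE)
  expect_equal(unname(st2$median[1] - st$median[1]), 2, tolerance = 0.2)
})

test_that("PCA scores reproduce the SVD of the centered matrix", {
  set.seed(2)
  Y <- matrix(rnorm(12 * 9), 12, 9,
              dimnames = list(paste0("a", 1:12), paste0("g", 1:9)))
  p <- pca_scores(Y, 5)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  s <- svd(Yc)
  raw <- s$u[, 1:5] %*% diag(s$d[1:5])
  for (j in 1:5) {                         # equality up to sign
    expect_true(max(abs(p$scores[, j] - raw[, j])) < 1e-10 ||
                max(abs(p$scores[, j] + raw[, j])) < 1e-10)
  }
  expect_true(all(diff(p$sdev) <= 1e-12))
  # sign convention: largest-magnitude loading positive, deterministically
  expect_true(all(vapply(1:5, function(j) {
    v <- p$loadings[, j]; v[which.max(abs(v))] > 0
  }, logical(1))))
  # rank-1 matrix: PC1 explains everything
  r1 <- outer(rnorm(8), rnorm(6))
  pr <- pca_scores(r1, 2)
  expect_equal(pr$var_explained[1], 1, tolerance = 1e-12)
  # 3-assay toy: eigenvalues from the closed-form quadratic
  Y3 <- matrix(c(0, 1, 2, 0, 2, 1), 3, 2)
  C <- stats::cov(Y3)
  tr <- C[1, 1] + C[2, 2]; dt <- C[1, 1] * C[2, 2] - C[1, 2]^2
  lam <- (tr + c(1, -1) * sqrt(tr^2 - 4 * dt)) / 2
  expect_equal(pca_scores(Y3, 2)$sdev^2, lam, tolerance = 1e-12)
})

test_that("cumulative-PC regression R2 behaves like OLS", {
  set.seed(3)
  S <- matrix(rnorm(30 * 5), 30, 5)
  # covariate equal to PC1
  expect_equal(unname(r2_cumulative_pcs(S, S[, 1], 3)), rep(1, 3),
               tolerance = 1e-12)
  # covariate orthogonal to all scores
  v <- stats::residuals(stats::lm(rnorm(30) ~ S))
  expect_lt(max(r2_cumulative_pcs(S, v, 5)), 1e-10)
  # equals the explicit normal-equations solve, and is non-decreasing
  y <- rnorm(30)
  r2 <- r2_cumulative_pcs(S, y, 5)
  for (k in 1:5) {
    Xk <- cbind(1, S[, 1:k])
    bh <- solve(t(Xk) %*% Xk, t(Xk) %*% y)
    expect_equal(unname(r2[k]),
                 1 - sum((y - Xk %*% bh)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("vector correlation summarizes canonical correlations", {
  set.seed(4)
  # two labels perfectly separated along PC1
  S <- cbind(rep(c(-3, 3), each = 10), matrix(rnorm(40), 20, 2))
  labels <- rep(c("u", "v"), each = 10)
  expect_equal(vector_correlation(S, labels), 1, tolerance = 1e-9)
  # single score column: reduces to the regression R2 of the dummy
  dummy <- as.numeric(labels == "v")
  expect_equal(vector_correlation(S[, 1, drop = FALSE], labels),
               unname(r2_cumulative_pcs(S[, 1, drop = FALSE], dummy, 1)),
               tolerance = 1e-12)
  # appending score columns never decreases the value
  y <- rnorm(20)
  vals <- vapply(1:3, function(k) vector_correlation(S[, 1:k, drop = FALSE], y),
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  # random labels sit at the permutation-null level
  set.seed(5)
  S2 <- matrix(rnorm(100 * 3), 100, 3)
  lab2 <- sample(c("a", "b"), 100, replace = TRUE)
  v0 <- vector_correlation(S2, lab2)
  perms <- replicate(200, vector_correlation(S2, sample(lab2)))
  expect_lt(abs(v0 - mean(perms)), 3 * sd(perms))
})

test_that("silhouette separates clouds and is near zero for random labels", {
  set.seed(6)
  clouds <- rbind(matrix(rnorm(100 * 3, 0), 100, 3),
                  matrix(rnorm(100 * 3, 20), 100, 3))
  lab <- rep(c("a", "b"), each = 100)
  expect_gt(silhouette_mean(clouds, lab), 0.9)
  one <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(abs(silhouette_mean(one, sample(lab))), 0.1)
  expect_error(silhouette_mean(one, rep("a", 200)), "2 distinct")
})

test_that("ARI agrees with brute-force pair counting and is label-invariant", {
  set.seed(7)
  # exhaustive pair counting oracle on a 10-assay toy
  ari_brute <- function(x, y) {
    pairs <- utils::combn(length(x), 2)
    sx <- x[pairs[1, ]] == x[pairs[2, ]]
    sy <- y[pairs[1, ]] == y[pairs[2, ]]
    a <- sum(sx & sy); b <- sum(sx & !sy); c_ <- sum(!sx & sy); d <- sum(!sx & !sy)
    n <- length(sx)
    exp_idx <- (a + b) * (a + c_) / n
    ((a - exp_idx) / ((a + b + a + c_) / 2 - exp_idx))
  }
  x <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  y <- c(1, 1, 2, 2, 2, 3, 3, 3, 3, 1)
  expect_equal(mclust::adjustedRandIndex(x, y), ari_brute(x, y),
               tolerance = 1e-12)
  # perfectly separable clustering recovers the labels
  clouds <- rbind(matrix(rnorm(30 * 3, 0), 30, 3),
                  matrix(rnorm(30 * 3, 15), 30, 3))
  lab <- rep(c("a", "b"), each = 30)
  expect_equal(ari_by_label(clouds, lab, seed = 1L), 1)
  # renaming labels leaves the ARI unchanged
  lab2 <- c(a = "z", b = "q")[lab]
  expect_equal(ari_by_label(clouds, lab, seed = 1L),
               ari_by_label(clouds, lab2, seed = 1L))
  expect_error(ari_by_label(clouds[1:3, ], rep(c("a", "b"), 2)[1:3],
                            n_clusters = 4, seed = 1L), "fewer assays")
})

test_that("rank-sum DE p-values are calibrated and handle edge cases", {
  set.seed(8)
  # complete separation between groups of 5 and 5: the documented
  # normal-approximation p-value with continuity correction
  x <- matrix(c(1:5, 101:105), 10, 2)
  x[, 2] <- rnorm(10)
  res <- de_pvalues(x, rep(c("lo", "hi"), each = 5))
  z <- (25 - 5 * 5 / 2 - 0.5) / sqrt(5 * 5 * 11 / 12)
  expect_equal(unname(res$p_values[1]), 2 * stats::pnorm(-z), tolerance = 1e-10)
  expect_error(de_pvalues(x, rep("a", 10)), "2 levels")
  expect_error(de_pvalues(x, c("a", rep("b", 9))), ">= 2 assays")
  # paired variant requires equal sizes
  expect_no_error(de_pvalues(x, rep(c("lo", "hi"), each = 5), paired = TRUE))
  # rank tests are invariant to monotone transforms
  y <- matrix(rexp(40 * 20), 40, 20)
  g <- rep(c("a", "b"), each = 20)
  expect_equal(de_pvalues(y, g)$p_values, de_pvalues(log(y), g)$p_values,
               tolerance = 1e-12)
})

test_that("partial correlation matches residual-on-residual correlation", {
  set.seed(9)
  z <- rnorm(50); x <- z + rnorm(50); y <- -z + rnorm(50)
  pc <- partial_correlation(x, y, z)
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  expect_equal(pc, stats::cor(rx, ry), tolerance = 1e-10)
  # independent z: collapses to the plain correlation
  z2 <- stats::residuals(stats::lm(rnorm(50) ~ x + y))
  expect_equal(partial_correlation(x, y, z2), stats::cor(x, y), tolerance = 1e-10)
  # x = z: undefined, flagged
  expect_warning(out <- partial_correlation(x, y, x), "collinear")
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
  # spearman flavor equals the formula on ranks
  ps <- partial_correlation(x, y, z, method = "spearman")
  rxs <- rank(x); rys <- rank(y); rzs <- rank(z)
  ref <- (cor(rxs, rys) - cor(rxs, rzs) * cor(rys, rzs)) /
    sqrt((1 - cor(rxs, rzs)^2) * (1 - cor(rys, rzs)^2))
  expect_equal(ps, ref, tolerance = 1e-12)
})

test_that("signature scores span [0, 1] with the analytic normalization", {
  Y <- matrix(0, 2, 6, dimnames = list(c("a1", "a2"), paste0("g", 1:6)))
  Y[1, ] <- c(1, 2, 3, 4, 5, 6)
  Y[2, ] <- c(6, 5, 4, 3, 2, 1)
  # hand computation: set {g5, g6} has ranks {5, 6} in a1 -> score 1
  expect_equal(unname(signature_score(Y, c("g5", "g6"))["a1"]), 1)
  expect_equal(unname(signature_score(Y, c("g5", "g6"))["a2"]), 0)
  # set {g2, g5}: mean rank in a1 = 3.5 -> (3.5 - 1.5) / (6 - 2) = 0.5
  expect_equal(unname(signature_score(Y, c("g2", "g5"))["a1"]), 0.5)
  # the whole gene universe gives the constant 0.5
  expect_equal(unname(signature_score(Y, paste0("g", 1:6))), rep(0.5, 2))
  # invariance under monotone transforms of an assay
  set.seed(10)
  Y2 <- matrix(rexp(5 * 40), 5, 40, dimnames = list(NULL, paste0("g", 1:40)))
  gs <- paste0("g", c(3, 9, 17, 30))
  expect_equal(signature_score(Y2, gs), signature_score(Y2^3, gs),
               tolerance = 1e-12)
  expect_equal(signature_score(Y2, gs), signature_score(log(Y2 + 5), gs),
               tolerance = 1e-12)
  # purity score is 1 minus the union score
  expect_equal(purity_score(Y2, gs[1:2], gs[3:4]),
               1 - signature_score(Y2, gs), tolerance = 1e-12)
  expect_error(signature_score(Y2, "nope"), "intersect")
})

test_that("the assembled report carries every table keyed as documented", {
  sim <- make_fixture("tiny")
  Y <- log_counts(sim$counts)
  rep <- assess_normalization(
    Y, covariates = list(ls = sim$meta$log2_library_size),
    factors = list(plate = sim$meta$plate, biology = sim$meta$biology),
    de_groups = list(ls_half = rep(c("lo", "hi"), each = 6)),
    genesets = list(top = colnames(Y)[1:5]),
    seed = 1L, counts = sim$counts)
  expect_s3_class(rep, "assessment_report")
  expect_equal(nrow(rep$rle_per_assay), 12L)
  expect_true(all(rep$r2_by_cumulative_pc$r2 >= 0 &
                  rep$r2_by_cumulative_pc$r2 <= 1))
  expect_true(all(rep$vector_correlation_by_cumulative_pc$vector_correlation >= 0))
  expect_equal(sort(unique(rep$cluster_metrics$variable)), c("biology", "plate"))
  expect_true(all(rep$score_per_assay$score >= 0 & rep$score_per_assay$score <= 1))
  expect_equal(nrow(rep$de_fractions), 1L)
})
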