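mk_counts <- function(values, n_genes = 4L) {
  m <- length(values)
  counts <- matrix(rep(values, n_genes), m, n_genes,
                   dimnames = list(sprintf("a%02d", seq_len(m)),
                                   paste0("g", seq_len(n_genes))))
  counts
}

test_that("assay filters remove exactly the hand-enumerated records", {
  # 10 plates of 5 assays, equal library sizes: nothing removed
  counts <- mk_counts(rep(100, 50))
  meta <- tibble::tibble(assay_id = rownames(counts),
                         plate = rep(paste0("P", 1:10), each = 5))
  res <- filter_assays(counts, meta, "plate")
  expect_equal(nrow(res$report$assays_removed), 0L)
  expect_equal(nrow(res$counts), 50L)
  # one plate of 2 assays among plates of 5: exactly those 2, reason small-plate
  meta2 <- tibble::tibble(assay_id = rownames(counts),
                          plate = c(rep(paste0("P", 1:9), each = 5),
                                    rep("tinyplate", 5))[1:50])
  meta2$plate[49:50] <- "P10"; meta2$plate[46:48] <- "P9"
  res2 <- filter_assays(counts, meta2, "plate")
  expect_setequal(res2$report$assays_removed$assay_id, rownames(counts)[49:50])
  expect_equal(unique(res2$report$assays_removed$reason), "small-plate")
  # library sizes {2^10 x 9 assays, 2^1 x 1}: the outlier goes by the MAD rule
  # (log2 sizes: nine at 10, one at 1; median 10, MAD 0, so 1 < 10 - 3*0)
  counts3 <- mk_counts(c(rep(2^10 / 4, 9), 2^1 / 4) - 0.25, n_genes = 4L)
  counts3 <- round(counts3)
  meta3 <- tibble::tibble(assay_id = rownames(counts3), plate = rep("P1", 10))
  res3 <- filter_assays(counts3, meta3, "plate")
  expect_equal(res3$report$assays_removed$assay_id, "a10")
  expect_equal(res3$report$assays_removed$reason, "low-library-size")
  # removing everything is an error
  expect_error(filter_assays(counts3[1:2, ], meta3[1:2, ], "plate",
                             min_plate_size = 5), "all assays removed")
})

test_that("gene filter applies the inclusive-boundary low-expression rule", {
  counts <- matrix(0, 10, 4,
                   dimnames = list(sprintf("a%02d", 1:10), paste0("g", 1:4)))
  counts[, 2] <- c(15, 15, 0, 0, 0, 0, 0, 0, 0, 0)  # exactly 20%: kept
  counts[, 3] <- c(15, 0, 0, 0, 0, 0, 0, 0, 0, 0)   # 10%: removed
  counts[, 4] <- 100
  res <- filter_genes(counts)
  expect_setequal(colnames(res$counts), c("g2", "g4"))
  expect_setequal(res$report$genes_removed$gene_id, c("g1", "g3"))
  expect_equal(unique(res$report$genes_removed$reason), "low-expression")
  # group-aware: judged in the smallest group
  counts2 <- matrix(100, 10, 2,
                    dimnames = list(sprintf("a%02d", 1:10), c("ok", "dropme")))
  groups <- rep(c("big", "small"), c(7, 3))
  counts2[8:10, "dropme"] <- 0                       # silent in the small group
  res2 <- filter_genes(counts2, groups = groups)
  expect_equal(colnames(res2$counts), "ok")
  # designed 10-gene pass/fail pattern matches hand enumeration
  set.seed(1)
  pat <- matrix(0, 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
  keep_true <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  for (j in 1:10) pat[seq_len(if (keep_true[j]) 5L else 3L), j] <- 20
  res3 <- filter_genes(pat, min_count = 15, min_fraction = 0.2)
  expect_setequal(colnames(res3$counts), paste0("g", which(keep_true)))
  expect_error(filter_genes(matrix(0, 4, 2)), "all genes removed")
})

test_that("matrix readers and writers round-trip across formats", {
  dir <- withr::local_tempdir()
  set.seed(2)
  M <- matrix(rpois(6 * 4, 30), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("g", 1:4)))
  for (fmt in c("tsv", "csv", "mtx")) {
    path <- file.path(dir, paste0("m.", fmt))
    write_counts(M, path)
    back <- read_counts(path)
    expect_equal(back, M, ignore_attr = FALSE, tolerance = 1e-12)
  }
  # real values to 1e-12
  Mr <- M + matrix(runif(24), 6, 4)
  write_counts(Mr, file.path(dir, "r.tsv"))
  expect_equal(read_counts(file.path(dir, "r.tsv")), Mr, tolerance = 1e-12)
  # transposed layout round-trips through the flag
  write_counts(M, file.path(dir, "t.tsv"), genes_in_rows = TRUE)
  expect_equal(read_counts(file.path(dir, "t.tsv"), genes_in_rows = TRUE), M)
  # mtx without sidecars is an error
  writeLines("%%MatrixMarket matrix coordinate real general\n1 1 1\n1 1 1.0",
             file.path(dir, "bad.mtx"))
  expect_error(read_counts(file.path(dir, "bad.mtx")), "sidecar")
})

test_that("metadata and gene-set files are parsed strictly", {
  dir <- withr::local_tempdir()
  meta <- tibble::tibble(assay_id = c("a1", "a2"), plate = c("P1", "P1"))
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_equal(read_metadata(file.path(dir, "meta.tsv"))$plate, c("P1", "P1"))
  utils::write.table(rbind(meta, meta), file.path(dir, "dup.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_metadata(file.path(dir, "dup.tsv")), "duplicated")
  # GMT round trip and malformed-line diagnostics
  sets <- list(sig1 = c("g1", "g2", "g3"), sig2 = c("g9", "g4"))
  write_geneset(sets, file.path(dir, "s.gmt"))
  expect_equal(read_geneset(file.path(dir, "s.gmt")), sets)
  writeLines(c("ok\tna\tg1\tg2", "broken\tonly-two-fields"),
             file.path(dir, "bad.gmt"))
  expect_error(read_geneset(file.path(dir, "bad.gmt")), "line 2")
  # one-per-line lists
  write_geneset(c("g5", "g6"), file.path(dir, "plain.txt"))
  expect_equal(read_geneset(file.path(dir, "plain.txt")), c("g5", "g6"))
})

test_that("the command-line surface drives the whole pipeline on disk", {
  dir <- withr::local_tempdir()
  cli <- function(...) ruvprps:::cli_main(c(...))
  cli("simulate", "--fixture", "tiny", "--out", file.path(dir, "sim"))
  expect_true(file.exists(file.path(dir, "sim", "counts.tsv")))
  cli("filter", "--counts", file.path(dir, "sim", "counts.tsv"),
      "--metadata", file.path(dir, "sim", "metadata.tsv"),
      "--plate", "plate", "--min-count", "5", "--min-fraction", "0.2",
      "--out", file.path(dir, "filt"))
  expect_true(file.exists(file.path(dir, "filt", "counts.tsv")))
  cli("select-controls", "--counts", file.path(dir, "filt", "counts.tsv"),
      "--metadata", file.path(dir, "filt", "metadata.tsv"),
      "--biology", "biology", "--rank-count", "20",
      "--out", file.path(dir, "controls.txt"))
  expect_length(read_geneset(file.path(dir, "controls.txt")), 20L)
  cli("build-prps", "--counts", file.path(dir, "filt", "counts.tsv"),
      "--metadata", file.path(dir, "filt", "metadata.tsv"),
      "--biology", "biology", "--recipe", "batch", "--batch", "plate",
      "--min-per-batch", "2", "--out", file.path(dir, "prps"))
  expect_true(file.exists(file.path(dir, "prps", "prps.json")))
  cli("normalize", "--counts", file.path(dir, "filt", "counts.tsv"),
      "--metadata", file.path(dir, "filt", "metadata.tsv"),
      "--controls", file.path(dir, "controls.txt"),
      "--prps", file.path(dir, "prps"), "--k", "1",
      "--out", file.path(dir, "norm"))
  adj <- read_counts(file.path(dir, "norm", "adjusted.tsv"))
  filt <- read_counts(file.path(dir, "filt", "counts.tsv"))
  expect_equal(dim(adj), dim(filt))
  cli("assess", "--counts", file.path(dir, "norm", "adjusted.tsv"),
      "--log-input", "--metadata", file.path(dir, "filt", "metadata.tsv"),
      "--covariates", "log2_library_size", "--factors", "plate,biology",
      "--seed", "1", "--out", file.path(dir, "report"))
  expect_true(file.exists(file.path(dir, "report",
                                    "r2_by_cumulative_pc.tsv")))
  expect_error(cli("unknown-cmd", "--out", "x"), "unknown command")
})
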