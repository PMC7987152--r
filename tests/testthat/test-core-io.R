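test_that("expression tables round-trip through write/read", {
  m <- random_expr(5, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, path)
  m2 <- read_expression_table(path)
  expect_identical(dimnames(m2), dimnames(m))
  expect_lt(max(abs(m2 - m)), 1e-12)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_expression_table(m, csv)
  expect_lt(max(abs(read_expression_table(csv) - m)), 1e-12)

  tr <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE)
  write.table(df, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_lt(max(abs(read_expression_table(tr, "samples_in_rows") - m)), 1e-12)
})

test_that("duplicate gene rows collapse by mean, bad cells and samples error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t5", "gA\t3\t7", "gB\t0\t1"), path)
  expect_warning(m <- read_expression_table(path), "dupl")
  expect_equal(unname(m["gA", ]), c(2, 6))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\tx", "gB\t0\t1"), bad)
  expect_error(read_expression_table(bad), "non-numeric.*gA.*s2")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts1", "gA\t1\t2", "gB\t0\t1"), dup)
  expect_error(read_expression_table(dup), "duplicate sample")
})

test_that("MTX datasets round-trip and enforce their contract", {
  cfg <- small_config()
  sc <- simulate_single_cell(cfg)$dataset
  dir <- withr::local_tempdir()
  write_mtx_dataset(sc, dir)
  sc2 <- read_mtx_dataset(file.path(dir, "counts.mtx"), file.path(dir, "genes.tsv"),
                          file.path(dir, "cells.tsv"), file.path(dir, "labels.tsv"))
  expect_equal(dim(sc2), dim(sc))
  expect_identical(sc2$cell_cluster, sc$cell_cluster)
  expect_equal(as.matrix(sc2$counts), as.matrix(sc$counts), ignore_attr = TRUE)

  # cell missing from the label table is dropped
  labels <- read.delim(file.path(dir, "labels.tsv"))
  write.table(labels[-1L, ], file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_message(sc3 <- read_mtx_dataset(file.path(dir, "counts.mtx"),
                                         file.path(dir, "genes.tsv"),
                                         file.path(dir, "cells.tsv"),
                                         file.path(dir, "labels.tsv")),
                 "dropping 1")
  expect_equal(ncol(sc3$counts), ncol(sc$counts) - 1L)

  # sidecar length mismatch
  writeLines(rownames(sc$counts)[-1L], file.path(dir, "genes.tsv"))
  expect_error(read_mtx_dataset(file.path(dir, "counts.mtx"), file.path(dir, "genes.tsv"),
                                file.path(dir, "cells.tsv"), file.path(dir, "labels.tsv")),
               "disagree")
})

test_that("fractional counts in an MTX file are rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 2", "1 1 2.5", "2 2 1"), file.path(dir, "m.mtx"))
  writeLines(c("gA", "gB"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.tsv"))
  write.table(data.frame(cell_id = c("c1", "c2"), cell_cluster = "x", donor_id = "d"),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mtx_dataset(file.path(dir, "m.mtx"), file.path(dir, "genes.tsv"),
                                file.path(dir, "cells.tsv"), file.path(dir, "labels.tsv")),
               "non-integer count")
})

test_that("GMT files parse, round-trip and reject malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tna\tA\tB", path)
  sets <- read_gmt(path)
  expect_named(sets, "S1")
  expect_equal(as.character(sets$S1), c("A", "B"))

  three <- list(a = c("g1", "g2"), b = c("g3", "g2", "g9"), c = "g4")
  write_gmt(three, path)
  back <- read_gmt(path)
  expect_identical(lapply(back, as.character), three)

  writeLines(character(0), path)
  expect_length(read_gmt(path), 0L)

  writeLines("S1\tna", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("top-variable-gene selection matches a brute-force variance sort", {
  m <- random_expr(100, 12, seed = 7)
  sel <- select_top_variable_genes(m, 5)
  v <- apply(m, 1, var)
  expect_setequal(rownames(sel), names(sort(v, decreasing = TRUE))[1:5])

  m2 <- rbind(A = c(0, 4, 0, 4), B = c(0, 1, 0, 1), C = c(1, 1, 1, 1))
  colnames(m2) <- paste0("s", 1:4)
  expect_identical(rownames(select_top_variable_genes(m2, 1)), "A")
  expect_identical(select_top_variable_genes(m2, 10), m2)
})

test_that("auroc agrees with exhaustive pair counting and its closed forms", {
  expect_equal(auroc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auroc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "positive and.*negative")

  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    s <- sample(0:5, n, replace = TRUE) + round(runif(n), 2)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(auroc(s, y), oracle_auroc(s, y))
    # invariance under strictly increasing transform, and complement rule
    expect_equal(auroc(exp(s), y), auroc(s, y))
  }
  s <- rnorm(20); y <- rep(c(TRUE, FALSE), 10)
  expect_equal(auroc(s, y) + auroc(-s, y), 1)
})

test_that("adjusted Rand index matches the mclust reference", {
  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:3, 25, replace = TRUE)
    b <- sample(letters[1:4], 25, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:2, c("x", "y")), 1)
})
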