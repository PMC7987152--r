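test_that("identical groups give zero log fold changes", {
  m <- random_expr(10, 8, seed = 1)
  m2 <- cbind(m, m)
  colnames(m2) <- sprintf("s%03d", 1:16)
  de <- differential_expression(m2, rep(c("a", "b"), each = 8))
  expect_equal(de$log2fc, rep(0, 10))
})

test_that("ordinary least squares matches per-gene lm fits", {
  m <- random_expr(12, 20, seed = 5)
  grp <- rep(c("a", "b"), each = 10)
  cov <- data.frame(smoking = rbinom(20, 1, 0.5), gender = rbinom(20, 1, 0.5))
  de <- differential_expression(m, grp, cov)
  for (i in c(1, 6, 12)) {
    fit <- summary(lm(m[i, ] ~ I(grp == "b") + cov$smoking + cov$gender))
    expect_equal(de$log2fc[i], unname(coef(fit)[2, 1]))
    expect_equal(de$t_statistic[i], unname(coef(fit)[2, 3]))
    expect_equal(de$p[i], unname(coef(fit)[2, 4]))
  }
})

test_that("the group coefficient equals the mean difference under orthogonal covariates", {
  m <- random_expr(15, 12, seed = 6)
  grp <- rep(c("a", "b"), each = 6)
  cov <- data.frame(x = rep(c(0, 1), 6))  # balanced across groups
  de <- differential_expression(m, grp, cov)
  diff <- rowMeans(m[, grp == "b"]) - rowMeans(m[, grp == "a"])
  expect_equal(de$log2fc, unname(diff))
})

test_that("differential expression is calibrated under the global null", {
  set.seed(33)
  m <- matrix(rnorm(2000 * 40), 2000, 40,
              dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%03d", 1:40)))
  cov <- data.frame(smoking = rbinom(40, 1, 0.5), gender = rbinom(40, 1, 0.5))
  de <- differential_expression(m, rep(c("a", "b"), each = 20), cov)
  expect_gt(mean(de$p < 0.05), 0.04)
  expect_lt(mean(de$p < 0.05), 0.06)
})

test_that("covariate adjustment absorbs confounded effects", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 30
    smoking <- rbinom(n, 1, 0.5)
    # group assignment correlated with smoking; gene driven by smoking only
    grp <- ifelse(runif(n) < 0.2 + 0.6 * smoking, "b", "a")
    if (min(table(grp)) < 3) return(NA)
    m <- matrix(rnorm(5 * n), 5, n,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
    m[1, ] <- m[1, ] + 2 * smoking
    de <- differential_expression(m, grp, data.frame(smoking = smoking))
    de$adj_p[de$gene_id == "g1"] < 0.05
  }, logical(1L))
  expect_lte(mean(hits, na.rm = TRUE), 0.10)
})

test_that("BH adjustment reproduces the step-up rule and is order-invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(2)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(diff(bh_adjust(sort(p))) >= 0))
})

test_that("log-fold-change replication handles self, negation and scarcity", {
  de <- tibble::tibble(gene_id = paste0("g", 1:20),
                       log2fc = seq(-3, 3, length.out = 20),
                       adj_p = rep(c(0.001, 0.5), 10))
  self <- logfc_replication(de, de)
  expect_equal(self$r, 1)
  neg <- dplyr::mutate(de, log2fc = -log2fc)
  expect_equal(logfc_replication(de, neg)$r, -1)
  few <- dplyr::mutate(de, adj_p = 1)
  expect_error(logfc_replication(de, few), "insufficient replication set")
})

test_that("replicated synthetic cohorts agree on subset log fold changes", {
  cfg <- sim_config()
  cohorts <- simulate_replication_cohorts(cfg, seed_a = 41, seed_b = 42)
  des <- lapply(cohorts, function(co) {
    cases <- co$metadata$sample_id[co$metadata$diagnosis == "case"]
    differential_expression(
      co$expr[, cases], co$truth$subset_labels[cases],
      co$metadata[match(cases, co$metadata$sample_id), c("smoking", "gender")])
  })
  rep_r <- logfc_replication(des$a, des$b)
  expect_gte(rep_r$r, 0.8)
  expect_gte(rep_r$n_genes, 3)
})

test_that("Dunn z agrees with the literal formula and flags extreme separation", {
  # 8 per group: large enough that even adjacent contrasts clear 0.05 under
  # the rank-based Dunn z
  vals <- c(1:8, 101:108, 201:208)
  grp <- rep(c("a", "b", "c"), each = 8)
  gc <- score_group_test(vals, grp)
  expect_true(all(gc$contrasts$adj_p < 0.05))
  for (i in seq_len(nrow(gc$contrasts))) {
    expect_equal(gc$contrasts$dunn_z[i],
                 oracle_dunn_z(vals, grp, gc$contrasts$group_a[i],
                               gc$contrasts$group_b[i]))
  }
  expect_equal(gc$omnibus$kw_statistic,
               unname(kruskal.test(vals, factor(grp))$statistic))

  # two identical groups give a zero contrast
  vals2 <- c(1, 2, 3, 1, 2, 3, 9, 10, 11)
  gc2 <- score_group_test(vals2, rep(c("a", "b", "c"), each = 3))
  ab <- dplyr::filter(gc2$contrasts, group_a == "a", group_b == "b")
  expect_equal(ab$dunn_z, 0)

  # ties: oracle agreement with many duplicated values
  set.seed(8)
  vals3 <- sample(1:4, 24, replace = TRUE)
  grp3 <- rep(c("a", "b", "c"), 8)
  gc3 <- score_group_test(vals3, grp3)
  for (i in seq_len(nrow(gc3$contrasts))) {
    expect_equal(gc3$contrasts$dunn_z[i],
                 oracle_dunn_z(vals3, grp3, gc3$contrasts$group_a[i],
                               gc3$contrasts$group_b[i]))
  }
  expect_error(score_group_test(1:5, c("a", "a", "a", "b", "b")), "at least 3")
})

test_that("Kruskal-Wallis keeps its nominal size under the null", {
  set.seed(44)
  rej <- mean(replicate(300, {
    score_group_test(rnorm(30), rep(c("x", "y", "z"), each = 10))$omnibus$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("signature score tests run over all rows of a score matrix", {
  scores <- matrix(rnorm(20), 2, 10,
                   dimnames = list(c("sigA", "sigB"), paste0("s", 1:10)))
  out <- score_group_tests(scores, rep(c("g1", "g2"), each = 5))
  expect_identical(nrow(out), 2L)
  expect_true(all(c("signature", "kw_p", "dunn_z", "adj_p") %in% names(out)))
})
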