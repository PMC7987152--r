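test_that("an exclusive marker tops the one-vs-rest ranking", {
  sc <- toy_sc()
  rk <- rank_markers(sc, "A")
  expect_identical(rk$gene_id[1L], "g001")
  expect_lt(rk$adj_p[1L], 1e-6)
  expect_gt(rk$effect[1L], 1)
  expect_error(rank_markers(sc, "absent"), "not present")
})

test_that("the rank-sum approximation tracks wilcox.test", {
  cfg <- small_config(n_genes = 60L, marker_log2fc = 1.5)
  sc <- simulate_single_cell(cfg, seed = 7)$dataset
  rk <- rank_markers(sc, "tcell",
                     signature_params(de_adj_p_max = 1, require_upregulated = FALSE))
  X <- lognormalize_counts(sc)
  pos <- sc$cell_cluster == "tcell"
  for (g in sample(rk$gene_id, 8)) {
    ref <- suppressWarnings(wilcox.test(X[g, pos], X[g, !pos], correct = TRUE))$p.value
    expect_equal(rk$p[rk$gene_id == g], ref, tolerance = 0.02)
  }
})

test_that("planted markers are recovered near the top of the ranking", {
  cfg <- small_config(marker_log2fc = 3, cells_per_type_per_donor = 20L)
  sim <- simulate_single_cell(cfg, seed = 11)
  rk <- rank_markers(sim$dataset, "ciliated")
  top <- head(rk$gene_id, 2L * cfg$markers_per_type)
  recall <- mean(sim$truth$marker_map$ciliated %in% top)
  expect_gte(recall, 0.8)
})

test_that("gene-set AUROC matches hand-computed concordance on a toy table", {
  # 6 cells, 2 genes; z-scored mean score then pairwise concordance
  counts <- rbind(gA = c(5L, 4L, 3L, 1L, 0L, 0L),
                  gB = c(3L, 5L, 2L, 0L, 1L, 0L))
  colnames(counts) <- paste0("c", 1:6)
  sc <- sc_dataset(counts, cell_cluster = rep(c("T", "U"), each = 3),
                   donor_id = rep("d", 6))
  cache <- signature_cache(sc)
  score <- colMeans(cache$zscores[c("gA", "gB"), ])
  expect_equal(gene_set_auroc(sc, c("gA", "gB"), "T"),
               oracle_auroc(score, rep(c(TRUE, FALSE), each = 3)))

  sc2 <- toy_sc()
  expect_equal(gene_set_auroc(sc2, "g001", "A"), 1)
})

test_that("constant genes score 0 with a warning and give chance AUROC", {
  # all-zero genes stay constant after library-size normalization
  counts <- matrix(0L, 4, 8, dimnames = list(paste0("g", 1:4), paste0("c", 1:8)))
  counts[4, ] <- rpois(8, 3) + 1L
  sc <- sc_dataset(counts, cell_cluster = rep(c("A", "B"), 4),
                   donor_id = rep("d", 8))
  expect_warning(a <- gene_set_auroc(sc, c("g1", "g2"), "A"), "zero-variance")
  expect_equal(a, 0.5)
})

test_that("the minimal-prefix rule reproduces its worked example", {
  aucs <- c(0.70, 0.80, 0.90, 0.95, 0.951, 0.951)
  expect_identical(ipfsubsets:::minimal_prefix_length(aucs, 0.005, 5L), 5L)
  # without the floor the shortest epsilon-proximal prefix is 4
  expect_identical(ipfsubsets:::minimal_prefix_length(aucs, 0.005, 1L), 4L)
  # first gene already maximal -> floor applies
  expect_identical(ipfsubsets:::minimal_prefix_length(c(0.99, rep(0.9, 9)), 0.005, 5L), 5L)
})

test_that("greedy selection equals the exhaustive-prefix oracle", {
  set.seed(21)
  for (i in 1:30) {
    n_genes <- 12L
    counts <- matrix(rnbinom(n_genes * 40, mu = 2, size = 2), n_genes, 40,
                     dimnames = list(sprintf("g%03d", 1:n_genes), sprintf("c%03d", 1:40)))
    type <- sample(rep(c("A", "B"), each = 20))
    counts[1:3, type == "A"] <- counts[1:3, type == "A"] + rpois(sum(type == "A") * 3, 4)
    sc <- sc_dataset(counts, type, rep("d", 40))
    ranking <- tibble::tibble(cell_type = "A",
                              gene_id = sample(rownames(counts)))
    sig <- select_minimal_signature(ranking, sc)
    expect_identical(sig$genes, oracle_minimal_signature(ranking, sc))
    expect_identical(sig$genes, ranking$gene_id[seq_along(sig$genes)])
  }
})

test_that("shrinking epsilon never shortens the signature", {
  cfg <- small_config()
  sim <- simulate_single_cell(cfg, seed = 13)
  cache <- signature_cache(sim$dataset)
  rk <- rank_markers(sim$dataset, "myeloid", cache = cache)
  lens <- vapply(c(0.05, 0.01, 0.005, 0.001, 0), function(eps) {
    length(select_minimal_signature(rk, sim$dataset,
                                    signature_params(epsilon = eps),
                                    cache = cache)$genes)
  }, numeric(1L))
  expect_true(all(diff(lens) >= 0))
})

test_that("too-short rankings are refused", {
  sc <- toy_sc()
  rk <- rank_markers(sc, "A")
  expect_error(select_minimal_signature(head(rk, 3), sc), "insufficient markers")
})

test_that("signatures are derived for every type and recover planted markers", {
  cfg <- sim_config(n_genes = 400L,
                    cell_types = c("myeloid", "ciliated", "tcell"),
                    composition = rbind(control = c(0.34, 0.33, 0.33),
                                        subset1 = c(0.5, 0.2, 0.3),
                                        subset2 = c(0.2, 0.5, 0.3)),
                    markers_per_type = 10L, cells_per_type_per_donor = 20L,
                    sc_donors_per_group = c(control = 1L, subset1 = 1L, subset2 = 1L))
  sim <- simulate_single_cell(cfg, seed = 17)
  sigs <- build_all_signatures(sim$dataset)
  expect_named(sigs, c("ciliated", "myeloid", "tcell"), ignore.order = TRUE)
  for (t in names(sigs)) {
    recall <- mean(sigs[[t]]$genes %in% sim$truth$marker_map[[t]])
    expect_gte(recall, 0.8)
    expect_gte(sigs[[t]]$achieved_auroc, sigs[[t]]$max_prefix_auroc - 0.005)
  }

  # GMT round trip preserves the signatures
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(as_gene_sets(sigs), path)
  back <- read_gmt(path)
  expect_identical(lapply(back, as.character),
                   lapply(as_gene_sets(sigs), as.character))

  one_type <- sc_dataset(as.matrix(sim$dataset$counts),
                         rep("only", ncol(sim$dataset$counts)),
                         sim$dataset$donor_id)
  expect_error(build_all_signatures(one_type), "at least 2")
})

test_that("tidy and glance expose the signature set as tables", {
  cfg <- small_config()
  sigs <- build_all_signatures(simulate_single_cell(cfg, seed = 19)$dataset)
  td <- tidy(sigs)
  gl <- glance(sigs)
  expect_true(all(c("cell_type", "gene_id", "rank") %in% names(td)))
  expect_identical(nrow(gl), length(sigs))
  expect_identical(sum(gl$n_genes), nrow(td))
})
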