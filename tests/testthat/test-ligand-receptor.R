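test_that("cell-type percentages match an exhaustive tally", {
  counts <- matrix(1L, 3, 10, dimnames = list(paste0("g", 1:3), paste0("c", 1:10)))
  sc <- sc_dataset(counts,
                   cell_cluster = c(rep("ciliated", 2), rep("other", 8)),
                   donor_id = rep("d1", 10))
  pct <- celltype_percentages(sc)
  expect_equal(pct$fraction[pct$cell_type == "ciliated"], 0.2)
  expect_equal(sum(pct$fraction), 1)

  set.seed(12)
  sc2 <- sc_dataset(matrix(0L, 2, 60, dimnames = list(c("a", "b"), paste0("c", 1:60))),
                    cell_cluster = sample(c("x", "y", "z"), 60, replace = TRUE),
                    donor_id = sample(c("d1", "d2"), 60, replace = TRUE))
  pct2 <- celltype_percentages(sc2)
  for (i in seq_len(nrow(pct2))) {
    want <- sum(sc2$cell_cluster == pct2$cell_type[i] & sc2$donor_id == pct2$donor_id[i]) /
      sum(sc2$donor_id == pct2$donor_id[i])
    expect_equal(pct2$fraction[i], want)
  }
  sums <- tapply(pct2$fraction, pct2$donor_id, sum)
  expect_lt(max(abs(sums - 1)), 1e-12)

  glob <- celltype_percentages(sc2, per = "global")
  expect_equal(sum(glob$fraction), 1)
})

test_that("ciliated split applies the 20% rule with the boundary going high", {
  pct <- tibble::tibble(
    donor_id = rep(c("d1", "d2", "d3"), each = 2),
    cell_type = rep(c("cilA", "other"), 3),
    fraction = c(0.05, 0.95, 0.60, 0.40, 0.20, 0.80))
  sp <- split_by_ciliated_fraction(pct, "cilA", cutoff = 0.20)
  expect_equal(sp$ciliated_group[match(c("d1", "d2", "d3"), sp$donor_id)],
               c("Ciliated_low", "Ciliated_high", "Ciliated_high"))
  expect_error(split_by_ciliated_fraction(pct, "missing_type"), "none of the ciliated")
})

test_that("the ciliated split recovers planted donor subsets", {
  cfg <- sim_config(sc_donors_per_group = c(control = 4L, subset1 = 4L, subset2 = 4L))
  sim <- simulate_single_cell(cfg, seed = 21)
  pct <- celltype_percentages(sim$dataset)
  sp <- split_by_ciliated_fraction(pct, "ciliated")
  planted_high <- sim$truth$donor_group[sp$donor_id] == "subset2"
  expect_gte(adjusted_rand_index(sp$ciliated_group, planted_high), 0.9)
})

test_that("a planted exclusive ligand-receptor edge is found and scored", {
  set.seed(31)
  n <- 120
  type <- rep(c("A", "B", "C"), each = 40)
  counts <- matrix(rpois(20 * n, 1), 20, n,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("c%03d", 1:n)))
  counts["g01", ] <- ifelse(type == "A", rpois(n, 20), 0L)  # ligand only in A
  counts["g02", ] <- ifelse(type == "B", rpois(n, 20), 0L)  # receptor only in B
  sc <- sc_dataset(counts, type, rep("d", n))
  lr <- tibble::tibble(ligand = "g01", receptor = "g02")
  out <- score_lr_interactions(sc, lr, lr_params(n_permutations = 200, seed = 5))
  expect_identical(nrow(out), 1L)
  expect_identical(out$sender_type, "A")
  expect_identical(out$receiver_type, "B")
  expect_gt(out$z, 0)
  expect_lte(out$p_perm, 0.05)
  expect_gt(out$p_perm, 0)
})

test_that("degenerate inputs yield an empty interaction table with warnings", {
  counts <- matrix(0L, 3, 12, dimnames = list(paste0("g", 1:3), paste0("c", 1:12)))
  sc <- sc_dataset(counts, rep(c("A", "B"), 6), rep("d", 12))
  expect_warning(out <- score_lr_interactions(
    sc, tibble::tibble(ligand = "g1", receptor = "g2"),
    lr_params(n_permutations = 100, seed = 1)), "gating")
  expect_identical(nrow(out), 0L)
  expect_warning(out2 <- score_lr_interactions(
    sc, tibble::tibble(ligand = "nope", receptor = "nada"),
    lr_params(n_permutations = 100, seed = 1)), "maps")
  expect_identical(nrow(out2), 0L)
})

test_that("interaction scoring is reproducible under a fixed seed", {
  cfg <- small_config()
  sim <- simulate_single_cell(cfg, seed = 2)
  lr <- tibble::tibble(ligand = sim$truth$marker_map$myeloid[1:2],
                       receptor = sim$truth$marker_map$tcell[1:2])
  p <- lr_params(n_permutations = 100, seed = 9)
  a <- score_lr_interactions(sim$dataset, lr, p)
  b <- score_lr_interactions(sim$dataset, lr, p)
  expect_identical(a, b)
  expect_true(all(a$p_perm > 0))
})

test_that("the top-percentile filter matches a quantile oracle", {
  set.seed(41)
  base <- tibble::tibble(sender_type = sample(c("A", "B"), 40, TRUE),
                         receiver_type = "C",
                         ligand = paste0("l", 1:40), receptor = paste0("r", 1:40),
                         strength = runif(40), z = rnorm(40), p_perm = runif(40))
  kept <- top_decile_filter(base, percentile = 0.10)
  thr <- quantile(base$z, 0.9, names = FALSE)
  expect_setequal(kept$ligand, base$ligand[base$z >= thr])
  expect_true(all(kept$weight == kept$z))

  ten <- dplyr::slice(base, 1:10)
  expect_identical(nrow(top_decile_filter(ten, percentile = 0.10)), 1L)
  tied <- dplyr::mutate(ten, z = 1)
  expect_identical(nrow(top_decile_filter(tied, percentile = 0.10)), 10L)

  # monotone in percentile, and always a subset of the input
  k25 <- top_decile_filter(base, percentile = 0.25)
  expect_true(all(kept$ligand %in% k25$ligand))
  expect_lte(nrow(k25), nrow(base))

  onlyA <- top_decile_filter(base, percentile = 0.5, sender_types = "A")
  expect_true(all(onlyA$sender_type == "A"))
  expect_error(top_decile_filter(base[0, ]), "no interactions")
})
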