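# shared fixtures, generated in code

# small named expression matrix of iid normals
random_expr <- function(p = 20, n = 10, seed = 1) {
  set.seed(seed)
  matrix(rnorm(p * n), p, n,
         dimnames = list(sprintf("g%03d", seq_len(p)), sprintf("s%03d", seq_len(n))))
}

# toy single-cell dataset: two types, one perfect marker for type A
toy_sc <- function(seed = 1, n_genes = 30, cells_per_type = 20) {
  set.seed(seed)
  n <- 2 * cells_per_type
  counts <- matrix(rpois(n_genes * n, 2), n_genes, n,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("c%03d", seq_len(n))))
  type <- rep(c("A", "B"), each = cells_per_type)
  counts["g001", ] <- ifelse(type == "A", rpois(n, 30), 0)
  sc_dataset(counts, cell_cluster = type,
             donor_id = rep(c("d1", "d2"), times = cells_per_type))
}

# small simulation config for fast tests; dots override the shrunk defaults
small_config <- function(...) {
  args <- list(n_genes = 300L, markers_per_type = 8L,
               cells_per_type_per_donor = 12L,
               sc_donors_per_group = c(control = 1L, subset1 = 1L, subset2 = 1L),
               n_donors_per_group = c(control = 8L, subset1 = 8L, subset2 = 8L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# independent literal transcription of the GSVA chain (explicit loops),
# used as the reference oracle
oracle_gsva <- function(m, sets, tau = 1, mode = "max_diff") {
  p <- nrow(m); n <- ncol(m)
  Fm <- matrix(0, p, n, dimnames = dimnames(m))
  for (i in seq_len(p)) {
    h <- sd(m[i, ]) / 4
    for (j in seq_len(n)) Fm[i, j] <- mean(pnorm((m[i, j] - m[i, ]) / h))
  }
  out <- matrix(0, length(sets), n, dimnames = list(names(sets), colnames(m)))
  for (s in seq_along(sets)) {
    member <- rownames(m) %in% sets[[s]]
    for (j in seq_len(n)) {
      ord <- order(-Fm[, j], rownames(m))
      inset <- member[ord]
      w <- abs(p / 2 - seq_len(p))^tau
      num <- 0; den_in <- sum(w[inset]); cnt_out <- 0
      v <- numeric(p)
      for (l in seq_len(p)) {
        if (inset[l]) num <- num + w[l] else cnt_out <- cnt_out + 1
        v[l] <- num / den_in - cnt_out / (p - sum(member))
      }
      out[s, j] <- if (mode == "max_diff") {
        max(0, max(v)) + min(0, min(v))
      } else {
        v[which.max(abs(v))]
      }
    }
  }
  out
}

# exhaustive pairwise-concordance AUROC oracle
oracle_auroc <- function(scores, pos) {
  wins <- 0; total <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    total <- total + 1
    if (scores[i] > scores[j]) wins <- wins + 1
    else if (scores[i] == scores[j]) wins <- wins + 0.5
  }
  wins / total
}

# literal Dunn z for one contrast, computed from first principles
oracle_dunn_z <- function(values, groups, a, b) {
  r <- rank(values)
  N <- length(values)
  tabs <- table(values)
  tie <- sum(tabs^3 - tabs) / (12 * (N - 1))
  ra <- mean(r[groups == a]); rb <- mean(r[groups == b])
  na <- sum(groups == a); nb <- sum(groups == b)
  (ra - rb) / sqrt((N * (N + 1) / 12 - tie) * (1 / na + 1 / nb))
}

# exhaustive-prefix signature-selection oracle: evaluates every prefix AUROC
# via gene_set_auroc and applies the stated rule directly
oracle_minimal_signature <- function(ranking, sc, epsilon = 0.005, min_genes = 5L) {
  genes <- ranking$gene_id
  aucs <- vapply(seq_along(genes), function(k) {
    gene_set_auroc(sc, genes[seq_len(k)], ranking$cell_type[1L])
  }, numeric(1L))
  a_star <- max(aucs)
  len <- which(aucs >= a_star - epsilon)[1L]
  len <- max(len, min(min_genes, length(genes)))
  genes[seq_len(len)]
}
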