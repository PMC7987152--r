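#' Parameters for minimal-signature selection
#'
#' @param epsilon AUROC tolerance: the returned signature is the shortest
#'   ranking prefix whose AUROC is within `epsilon` of the best prefix AUROC.
#' @param min_genes minimum signature length; shorter optima are padded with
#'   the next-ranked genes.
#' @param max_genes cap on the number of prefixes evaluated.
#' @param de_adj_p_max BH-adjusted p cutoff for the marker ranking.
#' @param require_upregulated keep only positive-effect (upregulated) markers,
#'   as signatures are used downstream as enrichment gene sets.
#' @return list of class `signature_params`.
#' @export
signature_params <- function(epsilon = 0.005, min_genes = 5L, max_genes = 200L,
                             de_adj_p_max = 0.05, require_upregulated = TRUE) {
  stopifnot(epsilon >= 0, min_genes >= 1L, max_genes >= min_genes,
            de_adj_p_max > 0, de_adj_p_max <= 1)
  structure(list(epsilon = epsilon, min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 de_adj_p_max = de_adj_p_max,
                 require_upregulated = isTRUE(require_upregulated)),
            class = "signature_params")
}

# per-gene midranks across cells plus the tie correction term sum(t^3 - t);
# shared across every one-vs-rest comparison on the same matrix
rank_stats <- function(X) {
  n <- ncol(X)
  R <- matrix(0, nrow(X), n, dimnames = dimnames(X))
  tie_sum <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    r <- rank(X[i, ])
    R[i, ] <- r
    t_counts <- tabulate(match(r, unique(r)))
    tie_sum[i] <- sum(t_counts^3 - t_counts)
  }
  list(ranks = R, tie_sum = tie_sum)
}

#' Rank one-vs-rest marker genes for a cell type
#'
#' Per-gene two-sided Wilcoxon rank-sum test of the target cluster against
#' all other cells on log-normalized expression (`log2(1 + 1e4 * count /
#' cell_total)`), using the normal approximation with tie correction and
#' continuity correction. The effect size is `log2((mean_in + 1) /
#' (mean_out + 1))` of the linear normalized expression. Rows are filtered to
#' BH-adjusted p at most `de_adj_p_max` (and positive effect when
#' `require_upregulated`) and sorted by decreasing effect.
#'
#' @param sc an [sc_dataset()].
#' @param cell_type cluster label to contrast against the rest.
#' @param params a [signature_params()].
#' @param cache optional precomputed list from [signature_cache()] to reuse
#'   across cell types.
#' @return tibble with columns `cell_type`, `gene_id`, `effect`, `p`, `adj_p`.
#' @export
rank_markers <- function(sc, cell_type, params = signature_params(), cache = NULL) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (!cell_type %in% sc$cell_cluster) {
    stop(sprintf("cell type '%s' not present", cell_type), call. = FALSE)
  }
  in_grp <- sc$cell_cluster == cell_type
  n1 <- sum(in_grp); n2 <- sum(!in_grp)
  if (n1 < 3L || n2 < 3L) {
    stop("need at least 3 cells inside and outside the target type", call. = FALSE)
  }
  if (is.null(cache)) cache <- signature_cache(sc)
  N <- n1 + n2
  rank_sum_in <- cache$rank_stats$ranks %*% in_grp
  U <- as.vector(rank_sum_in) - n1 * (n1 + 1) / 2
  mu_U <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - cache$rank_stats$tie_sum / (N * (N - 1))))
  z <- (U - mu_U - sign(U - mu_U) * 0.5) / pmax(sigma, .Machine$double.eps)
  z[sigma == 0] <- 0
  p <- 2 * pnorm(-abs(z))
  p <- pmin(p, 1)

  mean_in <- as.vector(cache$linear_norm %*% in_grp) / n1
  mean_out <- as.vector(cache$linear_norm %*% (!in_grp)) / n2
  effect <- log2((mean_in + 1) / (mean_out + 1))

  out <- tibble::tibble(
    cell_type = cell_type,
    gene_id = rownames(sc$counts),
    effect = effect,
    p = p,
    adj_p = p.adjust(p, method = "BH")
  )
  out <- dplyr::filter(out, .data$adj_p <= params$de_adj_p_max)
  if (params$require_upregulated) out <- dplyr::filter(out, .data$effect > 0)
  dplyr::arrange(out, dplyr::desc(.data$effect), .data$gene_id)
}

#' Precompute shared per-dataset matrices for signature work
#'
#' Caches the log-normalized matrix, the linear normalized matrix, gene-wise
#' z-scores and the rank statistics so that per-type marker ranking and
#' prefix AUROC evaluation do not recompute them.
#'
#' @param sc an [sc_dataset()].
#' @return list with `lognorm`, `linear_norm`, `zscores`, `rank_stats`.
#' @export
signature_cache <- function(sc) {
  lognorm <- lognormalize_counts(sc)
  totals <- colSums(as.matrix(sc$counts))
  totals[totals == 0] <- 1
  linear_norm <- sweep(as.matrix(sc$counts), 2L, totals, "/") * 1e4
  mu <- rowMeans(lognorm)
  sdv <- sqrt(row_variances(lognorm))
  z <- (lognorm - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  list(lognorm = lognorm, linear_norm = linear_norm, zscores = z,
       zero_var = sdv == 0, rank_stats = rank_stats(lognorm))
}

#' AUROC of a gene set for discriminating one cell type
#'
#' Scores each cell by the mean of per-gene z-scored log-normalized
#' expression over the set (zero-variance genes contribute 0, with a
#' warning), then evaluates the AUROC of that score for membership in the
#' target type.
#'
#' @param sc an [sc_dataset()].
#' @param genes character vector of gene ids, all present in `sc`.
#' @param cell_type target cluster label.
#' @param cache optional [signature_cache()].
#' @return AUROC in `[0, 1]`.
#' @export
gene_set_auroc <- function(sc, genes, cell_type, cache = NULL) {
  stopifnot(inherits(sc, "sc_dataset"), length(genes) >= 1L)
  missing <- setdiff(genes, rownames(sc$counts))
  if (length(missing)) {
    stop(sprintf("gene(s) not in dataset: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cache)) cache <- signature_cache(sc)
  if (any(cache$zero_var[genes])) {
    warning("zero-variance gene(s) in set contribute 0 to every cell's score",
            call. = FALSE)
  }
  score <- colMeans(cache$zscores[genes, , drop = FALSE])
  auroc(score, sc$cell_cluster == cell_type)
}

#' Select the minimal signature from a marker ranking
#'
#' Evaluates the gene-set AUROC of every prefix of the ranking (up to
#' `max_genes`), finds the maximum prefix AUROC `A*`, and returns the
#' shortest prefix whose AUROC is at least `A* - epsilon`, extended to
#' `min_genes` when shorter.
#'
#' @param ranking a [rank_markers()] tibble.
#' @param sc the [sc_dataset()] the ranking came from.
#' @param params a [signature_params()].
#' @param cache optional [signature_cache()].
#' @return object of class `cell_signature`: list with `cell_type`, `genes`,
#'   `achieved_auroc`, `max_prefix_auroc`, `prefix_auroc`, `params`.
#' @export
select_minimal_signature <- function(ranking, sc, params = signature_params(),
                                     cache = NULL) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (nrow(ranking) < params$min_genes) {
    stop("insufficient markers: ranking shorter than min_genes", call. = FALSE)
  }
  if (is.null(cache)) cache <- signature_cache(sc)
  cell_type <- ranking$cell_type[1L]
  genes <- head(ranking$gene_id, params$max_genes)
  pos <- sc$cell_cluster == cell_type

  # cumulative z-sums make prefix scores O(1) each; dividing by the prefix
  # length is rank-preserving so it is skipped
  Z <- cache$zscores[genes, , drop = FALSE]
  cum <- apply(Z, 2L, cumsum)
  if (length(genes) == 1L) cum <- matrix(cum, nrow = 1L)
  prefix_auroc <- vapply(seq_along(genes),
                         function(k) auroc(cum[k, ], pos), numeric(1L))

  len <- minimal_prefix_length(prefix_auroc, params$epsilon, params$min_genes)
  structure(
    list(cell_type = cell_type,
         genes = genes[seq_len(len)],
         achieved_auroc = prefix_auroc[len],
         max_prefix_auroc = max(prefix_auroc),
         prefix_auroc = prefix_auroc,
         params = params),
    class = "cell_signature"
  )
}

# the selection rule on a vector of prefix AUROCs, shared with the tests'
# exhaustive oracle contract
minimal_prefix_length <- function(prefix_auroc, epsilon, min_genes) {
  a_star <- max(prefix_auroc)
  len <- which(prefix_auroc >= a_star - epsilon)[1L]
  max(len, min(min_genes, length(prefix_auroc)))
}

#' @export
print.cell_signature <- function(x, ...) {
  cat(sprintf("cell_signature '%s': %d genes, AUROC %.4f (max prefix %.4f)\n",
              x$cell_type, length(x$genes), x$achieved_auroc, x$max_prefix_auroc))
  invisible(x)
}

#' Derive minimal signatures for every cell type
#'
#' Runs [rank_markers()] and [select_minimal_signature()] for each cluster
#' label in the dataset. Types whose ranking fails (too few significant
#' markers) are skipped with a warning. Signatures may overlap across types.
#'
#' @param sc an [sc_dataset()] with at least 2 cell types.
#' @param params a [signature_params()].
#' @return object of class `signature_set`: named list of `cell_signature`.
#' @export
build_all_signatures <- function(sc, params = signature_params()) {
  stopifnot(inherits(sc, "sc_dataset"))
  types <- sort(unique(sc$cell_cluster))
  if (length(types) < 2L) stop("need at least 2 cell types", call. = FALSE)
  cache <- signature_cache(sc)
  out <- list()
  for (t in types) {
    sig <- tryCatch({
      rk <- rank_markers(sc, t, params, cache = cache)
      select_minimal_signature(rk, sc, params, cache = cache)
    }, error = function(e) {
      warning(sprintf("skipping cell type '%s': %s", t, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(sig)) out[[t]] <- sig
  }
  if (!length(out)) stop("no cell type yielded a signature", call. = FALSE)
  structure(out, class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set with %d signatures\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

#' Convert a signature set to plain gene sets
#'
#' @param sigs a `signature_set`.
#' @return named list of character vectors, suitable for [gsva_scores()] and
#'   [write_gmt()].
#' @export
as_gene_sets <- function(sigs) {
  stopifnot(inherits(sigs, "signature_set") || is.list(sigs))
  out <- lapply(sigs, function(s) {
    structure(s$genes,
              description = sprintf("auroc=%.4f", s$achieved_auroc))
  })
  names(out) <- vapply(sigs, function(s) s$cell_type, character(1L))
  out
}

#' @rdname ipfsubsets-tidiers
#' @method tidy signature_set
#' @export
tidy.signature_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), function(s) {
    tibble::tibble(cell_type = s$cell_type,
                   gene_id = s$genes,
                   rank = seq_along(s$genes),
                   achieved_auroc = s$achieved_auroc,
                   max_prefix_auroc = s$max_prefix_auroc)
  })
}

#' @rdname ipfsubsets-tidiers
#' @method glance signature_set
#' @export
glance.signature_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), function(s) {
    tibble::tibble(cell_type = s$cell_type,
                   n_genes = length(s$genes),
                   achieved_auroc = s$achieved_auroc,
                   max_prefix_auroc = s$max_prefix_auroc)
  })
}
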