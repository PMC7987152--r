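#' GSVA scoring parameters
#'
#' @param kcdf kernel for the per-gene cumulative density estimate:
#'   `"gaussian"` (continuous log-scale data, bandwidth `sd/4`), `"poisson"`
#'   (integer counts, rate `x + 0.5`) or `"ecdf"` (plain empirical CDF).
#' @param tau weight exponent on the symmetric rank statistic.
#' @param mode random-walk summary: `"max_diff"` (GSVA default,
#'   `max(0, max v) + min(0, min v)`) or `"abs_max"` (signed maximum
#'   deviation).
#' @param min_set_size,max_set_size bounds on set size after intersection
#'   with the matrix genes.
#' @return list of class `gsva_params`.
#' @export
gsva_params <- function(kcdf = c("gaussian", "poisson", "ecdf"), tau = 1,
                        mode = c("max_diff", "abs_max"),
                        min_set_size = 2L, max_set_size = 500L) {
  kcdf <- match.arg(kcdf)
  mode <- match.arg(mode)
  stopifnot(tau >= 0, min_set_size >= 1L, min_set_size <= max_set_size)
  structure(list(kcdf = kcdf, tau = tau, mode = mode,
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size)),
            class = "gsva_params")
}

#' Gaussian-kernel CDF estimate of one gene's expression
#'
#' `F(x_j) = (1/n) sum_k Phi((x_j - x_k) / h)` with bandwidth `h = sd(x)/4`.
#'
#' @param x numeric vector of one gene's expression across samples (n >= 2).
#' @return vector of estimates in (0, 1).
#' @export
kcdf_gaussian <- function(x) {
  stopifnot(length(x) >= 2L)
  h <- sd(x) / 4
  if (h == 0) stop("constant gene", call. = FALSE)
  rowMeans(pnorm(outer(x, x, "-") / h))
}

#' Poisson-kernel CDF estimate for integer counts
#'
#' `F(x_j) = (1/n) sum_k Ppois(x_j; lambda = x_k + r)` with continuity offset
#' `r = 0.5`.
#'
#' @param x non-negative integer vector (n >= 2).
#' @param offset continuity offset added to each rate.
#' @return vector of estimates in (0, 1).
#' @export
kcdf_poisson <- function(x, offset = 0.5) {
  stopifnot(length(x) >= 2L, all(x >= 0), all(x == round(x)))
  rowMeans(outer(x, x, function(q, lam) ppois(q, lambda = lam + offset)))
}

#' Empirical CDF estimate
#'
#' @param x numeric vector (n >= 2).
#' @return `F(x_j) =` fraction of values `<= x_j`.
#' @export
kcdf_ecdf <- function(x) {
  stopifnot(length(x) >= 2L)
  rowMeans(outer(x, x, ">="))
}

#' Within-sample ranking and symmetric rank weights
#'
#' For each sample, genes are ordered by decreasing kernel-CDF value (ties
#' broken by gene id so the ordering is deterministic); the gene at rank
#' `r` gets weight `|p/2 - r|^tau`, down-weighting mid-ranked genes.
#'
#' @param kcdf_matrix genes x samples matrix of kernel-CDF values with gene
#'   rownames.
#' @param tau weight exponent.
#' @return list with `order` (p x n matrix; column j holds the gene row
#'   indices of sample j from top to bottom rank) and `weight_ordered`
#'   (p x n weights aligned to `order`).
#' @export
rank_weight_transform <- function(kcdf_matrix, tau = 1) {
  p <- nrow(kcdf_matrix); n <- ncol(kcdf_matrix)
  ids <- rownames(kcdf_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(p))
  ord <- matrix(0L, p, n, dimnames = list(NULL, colnames(kcdf_matrix)))
  for (j in seq_len(n)) {
    ord[, j] <- order(-kcdf_matrix[, j], ids)
  }
  w <- abs(p / 2 - seq_len(p))^tau
  list(order = ord,
       weight_ordered = matrix(w, p, n, dimnames = list(NULL, colnames(kcdf_matrix))))
}

#' Weighted Kolmogorov-Smirnov-like enrichment walk
#'
#' Walks down one sample's gene ordering accumulating weighted hits inside
#' the set against a uniform penalty outside it:
#' `v(l) = sum_{i<=l, in set} w_i / sum_{in set} w_i - #(i<=l, not in set) / (p - m)`.
#'
#' @param order integer vector of gene indices, top rank first.
#' @param weights weights aligned to `order` positions.
#' @param gene_set logical vector over gene indices (or integer indices)
#'   marking set membership; must leave at least one gene outside the set.
#' @param mode `"max_diff"` or `"abs_max"`.
#' @return enrichment score in `[-1, 1]`.
#' @export
enrichment_walk <- function(order, weights, gene_set, mode = c("max_diff", "abs_max")) {
  mode <- match.arg(mode)
  p <- length(order)
  if (!is.logical(gene_set)) {
    gene_set <- seq_len(p) %in% gene_set
  }
  m <- sum(gene_set)
  if (m < 1L) stop("empty gene set", call. = FALSE)
  if (m >= p) stop("degenerate set: covers all genes", call. = FALSE)
  inset <- gene_set[order]
  w_in <- weights * inset
  denom_in <- sum(w_in)
  if (denom_in == 0) {
    # all set genes carry weight 0 (exact mid-ranks); fall back to unweighted
    w_in <- as.numeric(inset)
    denom_in <- m
  }
  v <- cumsum(w_in) / denom_in - cumsum(!inset) / (p - m)
  if (mode == "max_diff") {
    max(0, max(v)) + min(0, min(v))
  } else {
    v[which.max(abs(v))]
  }
}

#' GSVA enrichment scores of gene sets across samples
#'
#' From-scratch gene set variation analysis: per-gene kernel CDF estimation
#' across samples, within-sample ranking with symmetric rank weights, and a
#' weighted KS-like random walk per set and sample. Scores lie in `[-1, 1]`
#' and, with the Gaussian kernel, are invariant to per-gene positive affine
#' transforms of the input.
#'
#' @param m genes x samples expression matrix.
#' @param sets named list of character gene-id vectors.
#' @param params a [gsva_params()].
#' @return sets x samples numeric matrix of enrichment scores.
#' @export
gsva_scores <- function(m, sets, params = gsva_params()) {
  validate_expression_matrix(m)
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))

  const <- row_variances(m) == 0
  if (any(const)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(const)), call. = FALSE)
    m <- m[!const, , drop = FALSE]
  }
  p <- nrow(m); n <- ncol(m)

  kc <- matrix(0, p, n, dimnames = dimnames(m))
  kfun <- switch(params$kcdf, gaussian = kcdf_gaussian,
                 poisson = kcdf_poisson, ecdf = kcdf_ecdf)
  for (i in seq_len(p)) kc[i, ] <- kfun(m[i, ])

  rw <- rank_weight_transform(kc, tau = params$tau)

  keep <- list()
  for (nm in names(sets)) {
    idx <- which(rownames(m) %in% sets[[nm]])
    if (length(idx) >= p) stop("degenerate set: covers all genes", call. = FALSE)
    if (length(idx) < params$min_set_size || length(idx) > params$max_set_size) {
      warning(sprintf("skipping set '%s': %d mapped gene(s) outside [%d, %d]",
                      nm, length(idx), params$min_set_size, params$max_set_size),
              call. = FALSE)
      next
    }
    keep[[nm]] <- idx
  }
  if (!length(keep)) stop("no usable gene sets after size filtering", call. = FALSE)

  scores <- matrix(0, length(keep), n, dimnames = list(names(keep), colnames(m)))
  for (s in seq_along(keep)) {
    member <- seq_len(p) %in% keep[[s]]
    for (j in seq_len(n)) {
      scores[s, j] <- enrichment_walk(rw$order[, j], rw$weight_ordered[, j],
                                      member, mode = params$mode)
    }
  }
  scores
}

#' Tidy a scores-by-samples matrix into long form
#'
#' @param scores sets x samples matrix (e.g. from [gsva_scores()]).
#' @param metadata optional tibble with a `sample_id` column to join.
#' @return long tibble with `signature`, `sample_id`, `score` (plus metadata
#'   columns when supplied).
#' @export
tidy_scores <- function(scores, metadata = NULL) {
  out <- tibble::as_tibble(scores, rownames = "signature") |>
    tidyr::pivot_longer(-"signature", names_to = "sample_id", values_to = "score")
  if (!is.null(metadata)) out <- dplyr::left_join(out, metadata, by = "sample_id")
  out
}
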