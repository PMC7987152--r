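#' Consensus clustering parameters
#'
#' @param k_range integer vector of cluster numbers to evaluate (min 2).
#' @param n_resamples number of subsampling iterations.
#' @param item_subsample_fraction fraction of samples drawn (without
#'   replacement) per iteration.
#' @param base_method `"hierarchical"` (average linkage on 1 - Pearson
#'   correlation) or `"kmeans"`.
#' @param pac_lower,pac_upper bounds of the ambiguous consensus band used by
#'   the PAC score.
#' @param seed RNG seed; results are deterministic given it.
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(k_range = 2:6, n_resamples = 1000L,
                             item_subsample_fraction = 0.8,
                             base_method = c("hierarchical", "kmeans"),
                             pac_lower = 0.1, pac_upper = 0.9, seed = 1L) {
  base_method <- match.arg(base_method)
  stopifnot(min(k_range) >= 2L, n_resamples >= 1L,
            item_subsample_fraction > 0, item_subsample_fraction <= 1,
            pac_lower >= 0, pac_lower < pac_upper, pac_upper <= 1)
  structure(list(k_range = as.integer(sort(unique(k_range))),
                 n_resamples = as.integer(n_resamples),
                 item_subsample_fraction = item_subsample_fraction,
                 base_method = base_method,
                 pac_lower = pac_lower, pac_upper = pac_upper,
                 seed = as.integer(seed)),
            class = "consensus_params")
}

#' Consensus clustering of samples with PAC model selection
#'
#' Repeatedly subsamples the cohort, clusters each subsample with the base
#' method, and records for every sample pair the fraction of co-sampled
#' iterations in which they co-clustered. Final labels per `k` come from
#' average-linkage hierarchical clustering of `1 - consensus`. The PAC score
#' of each consensus matrix summarises how crisp the clustering is.
#'
#' @param m genes x samples expression matrix (typically pre-filtered with
#'   [select_top_variable_genes()]).
#' @param params a [consensus_params()].
#' @return object of class `consensus_result`: list with `per_k` (per k:
#'   `consensus` matrix, `labels`, `pac`), `sample_ids`, `params`.
#' @export
consensus_cluster <- function(m, params = consensus_params()) {
  validate_expression_matrix(m)
  n <- ncol(m)
  ks <- params$k_range
  if (n < max(ks) + 2L) stop("too few samples for the requested k range", call. = FALSE)
  n_sub <- ceiling(params$item_subsample_fraction * n)

  with_seed(params$seed, function() {
    co_sampled <- matrix(0, n, n)
    co_clustered <- lapply(ks, function(k) matrix(0, n, n))
    names(co_clustered) <- as.character(ks)

    for (b in seq_len(params$n_resamples)) {
      idx <- sort(sample.int(n, n_sub))
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      sub <- m[, idx, drop = FALSE]
      if (params$base_method == "hierarchical") {
        d <- stats::as.dist(1 - cor(sub))
        hc <- hclust(d, method = "average")
        for (k in ks) {
          cl <- cutree(hc, k = k)
          for (c in seq_len(k)) {
            members <- idx[cl == c]
            co_clustered[[as.character(k)]][members, members] <-
              co_clustered[[as.character(k)]][members, members] + 1
          }
        }
      } else {
        for (k in ks) {
          cl <- stats::kmeans(t(sub), centers = k, nstart = 1L)$cluster
          for (c in seq_len(k)) {
            members <- idx[cl == c]
            co_clustered[[as.character(k)]][members, members] <-
              co_clustered[[as.character(k)]][members, members] + 1
          }
        }
      }
    }

    never <- co_sampled == 0 & upper.tri(co_sampled)
    if (any(never)) {
      warning(sprintf("%d sample pair(s) never co-sampled; consensus set to 0",
                      sum(never)), call. = FALSE)
    }
    denom <- co_sampled
    denom[denom == 0] <- 1

    per_k <- lapply(ks, function(k) {
      cm <- co_clustered[[as.character(k)]] / denom
      diag(cm) <- 1
      cm <- (cm + t(cm)) / 2
      dimnames(cm) <- list(colnames(m), colnames(m))
      labels <- cutree(hclust(stats::as.dist(1 - cm), method = "average"), k = k)
      names(labels) <- colnames(m)
      list(consensus = cm, labels = labels,
           pac = pac_score(cm, params$pac_lower, params$pac_upper))
    })
    names(per_k) <- as.character(ks)
    structure(list(per_k = per_k, sample_ids = colnames(m), params = params),
              class = "consensus_result")
  })
}

#' Proportion of ambiguous clustering
#'
#' `PAC = F(u2) - F(u1)` where `F` is the empirical CDF of the off-diagonal
#' upper-triangle consensus entries; both endpoints use the weak inequality
#' (`<=`). Lower is crisper.
#'
#' @param consensus_matrix symmetric samples x samples matrix in `[0, 1]`.
#' @param u1,u2 band bounds.
#' @return PAC in `[0, 1]`.
#' @export
pac_score <- function(consensus_matrix, u1 = 0.1, u2 = 0.9) {
  stopifnot(is.matrix(consensus_matrix),
            nrow(consensus_matrix) == ncol(consensus_matrix))
  e <- consensus_matrix[upper.tri(consensus_matrix)]
  mean(e <= u2) - mean(e <= u1)
}

#' Choose the number of clusters by minimum PAC
#'
#' Returns the `k` with the smallest PAC score; ties go to the smallest `k`.
#' Callers may override the choice (the stratification analyses here fix
#' `k = 2`).
#'
#' @param result a [consensus_cluster()] result.
#' @return integer `k`.
#' @export
choose_k <- function(result) {
  stopifnot(inherits(result, "consensus_result"), length(result$per_k) >= 2L)
  pac <- vapply(result$per_k, `[[`, numeric(1L), "pac")
  ks <- as.integer(names(result$per_k))
  ks[which.min(pac)]  # which.min takes the first (smallest k) on ties
}

#' Extract subset labels for a given k
#'
#' @param result a [consensus_cluster()] result.
#' @param k cluster number present in the evaluated range.
#' @return named integer vector of labels (1..k) per sample.
#' @export
consensus_labels <- function(result, k) {
  stopifnot(inherits(result, "consensus_result"))
  kk <- as.character(k)
  if (!kk %in% names(result$per_k)) stop("k was not evaluated", call. = FALSE)
  result$per_k[[kk]]$labels
}

#' @rdname ipfsubsets-tidiers
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  purrr::map_dfr(names(x$per_k), function(kk) {
    tibble::tibble(k = as.integer(kk),
                   sample_id = x$sample_ids,
                   label = unname(x$per_k[[kk]]$labels))
  })
}

#' @rdname ipfsubsets-tidiers
#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(
    k = as.integer(names(x$per_k)),
    pac = vapply(x$per_k, `[[`, numeric(1L), "pac"),
    chosen = as.integer(names(x$per_k)) == choose_k(x)
  )
}
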