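#' Covariate-adjusted per-gene differential expression
#'
#' Ordinary least squares of each gene's expression on a two-level group
#' indicator plus optional covariates (the stratification analyses adjust
#' for smoking and gender). The reported `log2fc` is the group coefficient,
#' tested with a two-sided t-test and BH-adjusted across genes. No
#' empirical-Bayes variance moderation is applied.
#'
#' @param m genes x samples expression matrix (log2 scale).
#' @param labels two-level group vector aligned to columns of `m`; the
#'   coefficient is the second level minus the first (factor level order, or
#'   sorted unique order for character input).
#' @param covariates optional data frame of numeric covariates aligned to
#'   samples.
#' @return tibble with `gene_id`, `log2fc`, `t_statistic`, `p`, `adj_p`,
#'   `degenerate` (zero residual variance flag).
#' @export
differential_expression <- function(m, labels, covariates = NULL) {
  validate_expression_matrix(m)
  labels <- as.factor(labels)
  stopifnot(length(labels) == ncol(m))
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels", call. = FALSE)
  if (min(table(labels)) < 3L) stop("each group needs at least 3 samples", call. = FALSE)

  X <- cbind(intercept = 1, group = as.numeric(labels == levels(labels)[2L]))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == ncol(m))
    for (nm in colnames(covariates)) {
      X <- cbind(X, as.numeric(covariates[[nm]]))
      colnames(X)[ncol(X)] <- nm
    }
  }
  n <- nrow(X); q <- ncol(X)
  df <- n - q
  if (df <= 0L) stop("zero residual degrees of freedom", call. = FALSE)

  XtX_inv <- solve(crossprod(X))
  B <- XtX_inv %*% crossprod(X, t(m))       # coefficients x genes
  resid <- t(m) - X %*% B                   # samples x genes
  rss <- colSums(resid^2)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtX_inv["group", "group"])
  fc <- B["group", ]

  degenerate <- sigma2 < .Machine$double.eps
  tstat <- ifelse(se > 0, fc / se, ifelse(fc != 0, Inf, 0))
  p <- 2 * pt(-abs(tstat), df = df)
  p[degenerate] <- ifelse(fc[degenerate] != 0, 0, 1)

  tibble::tibble(
    gene_id = rownames(m),
    log2fc = unname(fc),
    t_statistic = unname(tstat),
    p = unname(p),
    adj_p = bh_adjust(unname(p)),
    degenerate = unname(degenerate)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement, delegated to
#' [stats::p.adjust()]; inputs are validated to lie in `[0, 1]`.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Cross-cohort log-fold-change replication
#'
#' Filters both differential-expression tables to
#' `|log2fc| > lfc_min & adj_p < fdr_max`, intersects the surviving genes,
#' and reports the Pearson correlation of the two log-fold-change vectors.
#'
#' @param de_a,de_b tibbles from [differential_expression()] (need columns
#'   `gene_id`, `log2fc`, `adj_p`).
#' @param lfc_min,fdr_max replication filters (strict inequalities).
#' @return one-row tibble with `r` and `n_genes`.
#' @export
logfc_replication <- function(de_a, de_b, lfc_min = 0.58, fdr_max = 0.05) {
  pass <- function(de) de$gene_id[abs(de$log2fc) > lfc_min & de$adj_p < fdr_max]
  shared <- intersect(pass(de_a), pass(de_b))
  if (length(shared) < 3L) stop("insufficient replication set", call. = FALSE)
  a <- de_a$log2fc[match(shared, de_a$gene_id)]
  b <- de_b$log2fc[match(shared, de_b$gene_id)]
  tibble::tibble(r = cor(a, b), n_genes = length(shared))
}

#' Kruskal-Wallis omnibus plus Dunn pairwise comparisons
#'
#' Compares a signature score (or any numeric response) across groups with
#' the tie-corrected Kruskal-Wallis test, followed by Dunn's rank-based
#' post-hoc z for every pair of groups, two-sided p-values BH-adjusted
#' within the family of contrasts.
#'
#' @param values numeric vector (e.g. one signature's scores).
#' @param groups group labels, at least two levels with >= 3 values each.
#' @return object of class `group_comparison`: list with `omnibus` (one-row
#'   tibble: `kw_statistic`, `p`, `n_groups`, `n`) and `contrasts` (tibble:
#'   `group_a`, `group_b`, `dunn_z`, `p`, `adj_p`).
#' @export
score_group_test <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  stopifnot(length(values) == length(groups), !anyNA(values))
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (min(table(groups)) < 3L) stop("each group needs at least 3 values", call. = FALSE)

  kw <- kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  t_counts <- tabulate(match(values, unique(values)))
  tie_term <- sum(t_counts^3 - t_counts) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  n_g <- table(groups)

  pairs <- utils::combn(levels(groups), 2L)
  z <- apply(pairs, 2L, function(ab) {
    a <- ab[1L]; b <- ab[2L]
    (mean_ranks[[a]] - mean_ranks[[b]]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[a]] + 1 / n_g[[b]]))
  })
  p <- 2 * pnorm(-abs(z))
  contrasts <- tibble::tibble(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    dunn_z = unname(z), p = unname(p), adj_p = bh_adjust(unname(p))
  )
  structure(
    list(omnibus = tibble::tibble(kw_statistic = unname(kw$statistic),
                                  p = kw$p.value,
                                  n_groups = nlevels(groups), n = N),
         contrasts = contrasts),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, p = %.3g (%d groups, n = %d)\n",
              x$omnibus$kw_statistic, x$omnibus$p, x$omnibus$n_groups, x$omnibus$n))
  print(x$contrasts)
  invisible(x)
}

#' @rdname ipfsubsets-tidiers
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$contrasts

#' @rdname ipfsubsets-tidiers
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) x$omnibus

#' Group comparisons for every signature in a score matrix
#'
#' Maps [score_group_test()] over the rows of a signatures x samples score
#' matrix.
#'
#' @param scores sets x samples matrix.
#' @param groups group labels aligned to columns.
#' @return tibble of Dunn contrasts with a `signature` column plus omnibus
#'   columns `kw_statistic` and `kw_p`.
#' @export
score_group_tests <- function(scores, groups) {
  purrr::map_dfr(rownames(scores), function(sig) {
    gc <- score_group_test(scores[sig, ], groups)
    dplyr::mutate(gc$contrasts, signature = sig,
                  kw_statistic = gc$omnibus$kw_statistic,
                  kw_p = gc$omnibus$p, .before = 1L)
  })
}
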