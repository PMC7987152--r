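#' Ligand-receptor scoring parameters
#'
#' @param ciliated_cutoff donor-level ciliated-cell fraction separating
#'   `Ciliated_low` from `Ciliated_high` (fraction >= cutoff is high).
#' @param expressed_fraction_min a gene counts as expressed in a cell type
#'   when nonzero in at least this fraction of the type's cells.
#' @param n_permutations label permutations for the null (>= 100).
#' @param top_percentile fraction of top-z interactions retained by
#'   [top_decile_filter()].
#' @param seed RNG seed for the permutations.
#' @return list of class `lr_params`.
#' @export
lr_params <- function(ciliated_cutoff = 0.20, expressed_fraction_min = 0.10,
                      n_permutations = 1000L, top_percentile = 0.10, seed = 1L) {
  stopifnot(ciliated_cutoff > 0, ciliated_cutoff < 1,
            expressed_fraction_min > 0, expressed_fraction_min < 1,
            top_percentile > 0, top_percentile < 1,
            n_permutations >= 100L)
  structure(list(ciliated_cutoff = ciliated_cutoff,
                 expressed_fraction_min = expressed_fraction_min,
                 n_permutations = as.integer(n_permutations),
                 top_percentile = top_percentile, seed = as.integer(seed)),
            class = "lr_params")
}

#' Read a two-column ligand-receptor pair table
#'
#' @param path tab-separated file with header `ligand` and `receptor`.
#' @return tibble with unique `ligand`, `receptor` rows.
#' @export
read_lr_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% colnames(df))) {
    stop("pair table needs columns 'ligand' and 'receptor'", call. = FALSE)
  }
  out <- tibble::as_tibble(df[, c("ligand", "receptor")])
  if (any(!nzchar(out$ligand)) || any(!nzchar(out$receptor))) {
    stop("empty gene name in pair table", call. = FALSE)
  }
  dplyr::distinct(out)
}

#' Cell-type percentages per donor
#'
#' @param sc an [sc_dataset()].
#' @param per `"donor"` for per-donor fractions (long tibble) or `"global"`
#'   for whole-dataset fractions.
#' @return tibble with `donor_id` (unless global), `cell_type`, `fraction`;
#'   fractions sum to 1 within each donor.
#' @export
celltype_percentages <- function(sc, per = c("donor", "global")) {
  per <- match.arg(per)
  stopifnot(inherits(sc, "sc_dataset"))
  if (per == "global") {
    tab <- table(sc$cell_cluster)
    return(tibble::tibble(cell_type = names(tab),
                          fraction = as.vector(tab) / sum(tab)))
  }
  tibble::tibble(donor_id = sc$donor_id, cell_type = sc$cell_cluster) |>
    dplyr::count(.data$donor_id, .data$cell_type) |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("donor_id", "cell_type", "fraction")
}

#' Split donors by their ciliated-cell fraction
#'
#' Sums each donor's fractions over the given ciliated cell types and labels
#' donors `Ciliated_high` when the summed fraction is at least `cutoff`,
#' `Ciliated_low` otherwise (the boundary value goes to high).
#'
#' @param percentages long tibble from [celltype_percentages()].
#' @param ciliated_types cell-type names counted as ciliated.
#' @param cutoff fraction threshold (default 0.20).
#' @return tibble with `donor_id`, `ciliated_fraction`, `ciliated_group`.
#' @export
split_by_ciliated_fraction <- function(percentages, ciliated_types, cutoff = 0.20) {
  stopifnot(length(ciliated_types) >= 1L)
  if (!any(ciliated_types %in% percentages$cell_type)) {
    stop("none of the ciliated types are present", call. = FALSE)
  }
  percentages |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::summarise(
      ciliated_fraction = sum(.data$fraction[.data$cell_type %in% ciliated_types])
    ) |>
    dplyr::mutate(ciliated_group = ifelse(.data$ciliated_fraction >= cutoff,
                                          "Ciliated_high", "Ciliated_low"))
}

#' Permutation-scored ligand-receptor interactions between cell types
#'
#' For every ligand-receptor pair and ordered (sender, receiver) cell-type
#' pair where the ligand is expressed in the sender and the receptor in the
#' receiver (nonzero in at least `expressed_fraction_min` of cells), the
#' interaction strength is the product of the mean log-normalized ligand
#' expression in the sender and receptor expression in the receiver. A null
#' distribution from shuffling cell-type labels yields a z-score and an
#' add-one permutation p-value.
#'
#' @param sc an [sc_dataset()] with at least 2 cell types.
#' @param lr_table tibble with `ligand`, `receptor` columns.
#' @param params an [lr_params()].
#' @return tibble with `sender_type`, `receiver_type`, `ligand`, `receptor`,
#'   `strength`, `z`, `p_perm`; empty (with a warning) when nothing passes
#'   the expression gating.
#' @export
score_lr_interactions <- function(sc, lr_table, params = lr_params()) {
  stopifnot(inherits(sc, "sc_dataset"))
  types <- sort(unique(sc$cell_cluster))
  if (length(types) < 2L) stop("need at least 2 cell types", call. = FALSE)
  lr <- dplyr::filter(lr_table,
                      .data$ligand %in% rownames(sc$counts),
                      .data$receptor %in% rownames(sc$counts))
  empty <- tibble::tibble(sender_type = character(), receiver_type = character(),
                          ligand = character(), receptor = character(),
                          strength = numeric(), z = numeric(), p_perm = numeric())
  if (!nrow(lr)) {
    warning("no ligand-receptor pair maps to the dataset", call. = FALSE)
    return(empty)
  }

  genes <- unique(c(lr$ligand, lr$receptor))
  X <- lognormalize_counts(sc)[genes, , drop = FALSE]
  grp <- factor(sc$cell_cluster, levels = types)
  ind <- stats::model.matrix(~ grp - 1)
  colnames(ind) <- types
  n_per_type <- colSums(ind)
  mean_by_type <- X %*% ind %*% diag(1 / n_per_type, length(types))
  colnames(mean_by_type) <- types
  expr_frac <- (X > 0) %*% ind %*% diag(1 / n_per_type, length(types))
  colnames(expr_frac) <- types

  # candidate edges: every ordered (sender, receiver) pair passing gating
  cand <- tidyr::expand_grid(pair_idx = seq_len(nrow(lr)),
                             sender_type = types, receiver_type = types) |>
    dplyr::mutate(ligand = lr$ligand[.data$pair_idx],
                  receptor = lr$receptor[.data$pair_idx]) |>
    dplyr::filter(
      expr_frac[cbind(.data$ligand, .data$sender_type)] >= params$expressed_fraction_min,
      expr_frac[cbind(.data$receptor, .data$receiver_type)] >= params$expressed_fraction_min
    )
  if (!nrow(cand)) {
    warning("no interaction passes the expression gating", call. = FALSE)
    return(empty)
  }
  strength <- mean_by_type[cbind(cand$ligand, cand$sender_type)] *
    mean_by_type[cbind(cand$receptor, cand$receiver_type)]

  B <- params$n_permutations
  li <- cbind(match(cand$ligand, genes), match(cand$sender_type, types))
  ri <- cbind(match(cand$receptor, genes), match(cand$receiver_type, types))
  null_ge <- numeric(nrow(cand))
  null_sum <- numeric(nrow(cand))
  null_sumsq <- numeric(nrow(cand))
  with_seed(params$seed, function() {
    for (b in seq_len(B)) {
      perm <- ind[sample.int(nrow(ind)), , drop = FALSE]
      Mp <- X %*% perm %*% diag(1 / n_per_type, length(types))
      s <- Mp[li] * Mp[ri]
      null_ge <<- null_ge + (s >= strength)
      null_sum <<- null_sum + s
      null_sumsq <<- null_sumsq + s^2
    }
  })
  null_mean <- null_sum / B
  null_sd <- sqrt(pmax(0, null_sumsq / B - null_mean^2) * B / (B - 1))
  z <- ifelse(null_sd > 0, (strength - null_mean) / null_sd, 0)

  tibble::tibble(
    sender_type = cand$sender_type, receiver_type = cand$receiver_type,
    ligand = cand$ligand, receptor = cand$receptor,
    strength = strength, z = z,
    p_perm = (1 + null_ge) / (B + 1)
  ) |>
    dplyr::arrange(dplyr::desc(.data$z))
}

#' Keep the top percentile of interactions by z-score
#'
#' Optionally restricts to given sender types, then retains interactions
#' whose score is at least the `1 - percentile` quantile within that
#' restriction (ties at the threshold are kept). The output doubles as a
#' chord-diagram edge table via its `weight` column.
#'
#' @param interactions tibble from [score_lr_interactions()].
#' @param by column used for ranking (default `"z"`).
#' @param percentile retained fraction (default 0.10 = top decile).
#' @param sender_types optional sender-type restriction.
#' @return filtered tibble with an added `weight` column (the ranking value).
#' @export
top_decile_filter <- function(interactions, by = "z", percentile = 0.10,
                              sender_types = NULL) {
  if (!nrow(interactions)) stop("no interactions to filter", call. = FALSE)
  if (!is.null(sender_types)) {
    interactions <- dplyr::filter(interactions, .data$sender_type %in% sender_types)
    if (!nrow(interactions)) stop("no interactions from the given sender types", call. = FALSE)
  }
  v <- interactions[[by]]
  thr <- quantile(v, 1 - percentile, names = FALSE)
  dplyr::mutate(interactions[v >= thr, , drop = FALSE], weight = .data[[by]])
}
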