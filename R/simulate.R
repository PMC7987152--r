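#' Simulation configuration for synthetic lung cohorts
#'
#' Builds the configuration object shared by the single-cell and bulk
#' simulators. The defaults encode a six-archetype lung (myeloid, ciliated
#' epithelium, B/plasma, T, endothelial, fibroblast) with 20 planted marker
#' genes per type at log2 fold change 3, and three donor groups: healthy
#' controls plus two planted IPF subsets whose bulk profiles are cell-type
#' composition mixtures — subset 1 myeloid-enriched, subset 2
#' ciliated/plasma-enriched and T-depleted.
#'
#' @param n_genes total number of genes.
#' @param cell_types character vector of cell-type names.
#' @param cells_per_type_per_donor expected cells per type per donor in the
#'   single-cell simulator (per-donor totals are this times the number of
#'   types; the split across types follows the donor group's composition).
#' @param markers_per_type planted markers per cell type (disjoint blocks).
#' @param marker_log2fc marker effect size, log2 units.
#' @param nb_mean,nb_dispersion negative-binomial baseline mean and size for
#'   single-cell counts.
#' @param n_donors_per_group named integer vector `control`, `subset1`,
#'   `subset2`: bulk cohort sizes.
#' @param sc_donors_per_group same, for the single-cell simulator.
#' @param composition groups x types matrix of cell-type proportions, rows
#'   summing to 1.
#' @param dirichlet_concentration per-sample proportions are drawn
#'   Dirichlet(concentration x group composition).
#' @param bulk_intensity linear-scale baseline intensity of the bulk
#'   pseudo-counts before the log2 transform.
#' @param bulk_noise_sd log2-scale Gaussian noise sd for bulk samples.
#' @param covariate_effect_sd sd of per-gene additive smoking/gender effects
#'   (log2 scale), applied to a random `covariate_gene_fraction` of genes.
#' @param covariate_gene_fraction fraction of genes carrying each covariate
#'   effect.
#' @param seed integer seed; every simulator call is deterministic given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       cell_types = c("myeloid", "ciliated", "bcell_plasma",
                                      "tcell", "endothelial", "fibroblast"),
                       cells_per_type_per_donor = 25L,
                       markers_per_type = 20L,
                       marker_log2fc = 3,
                       nb_mean = 0.5,
                       nb_dispersion = 2,
                       n_donors_per_group = c(control = 30L, subset1 = 30L, subset2 = 30L),
                       sc_donors_per_group = c(control = 3L, subset1 = 3L, subset2 = 3L),
                       composition = NULL,
                       dirichlet_concentration = 50,
                       bulk_intensity = 100,
                       bulk_noise_sd = 0.25,
                       covariate_effect_sd = 0.3,
                       covariate_gene_fraction = 0.1,
                       seed = 1L) {
  if (is.null(composition)) {
    composition <- rbind(
      control = c(myeloid = 0.20, ciliated = 0.10, bcell_plasma = 0.10,
                  tcell = 0.20, endothelial = 0.20, fibroblast = 0.20),
      subset1 = c(myeloid = 0.40, ciliated = 0.08, bcell_plasma = 0.08,
                  tcell = 0.14, endothelial = 0.15, fibroblast = 0.15),
      subset2 = c(myeloid = 0.12, ciliated = 0.30, bcell_plasma = 0.20,
                  tcell = 0.08, endothelial = 0.15, fibroblast = 0.15)
    )
    colnames(composition) <- cell_types[seq_len(ncol(composition))]
  }
  cfg <- list(
    n_genes = as.integer(n_genes), cell_types = cell_types,
    cells_per_type_per_donor = as.integer(cells_per_type_per_donor),
    markers_per_type = as.integer(markers_per_type),
    marker_log2fc = marker_log2fc,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    n_donors_per_group = n_donors_per_group,
    sc_donors_per_group = sc_donors_per_group,
    composition = composition,
    dirichlet_concentration = dirichlet_concentration,
    bulk_intensity = bulk_intensity,
    bulk_noise_sd = bulk_noise_sd,
    covariate_effect_sd = covariate_effect_sd,
    covariate_gene_fraction = covariate_gene_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  k <- length(cfg$cell_types)
  if (k < 2L) stop("need at least 2 cell types", call. = FALSE)
  if (cfg$markers_per_type * k > cfg$n_genes) {
    stop("markers_per_type x number of types exceeds n_genes", call. = FALSE)
  }
  if (!identical(dim(cfg$composition), c(3L, k)) &&
      !(nrow(cfg$composition) == 3L && ncol(cfg$composition) == k)) {
    stop("composition must be a 3-group x n-type matrix", call. = FALSE)
  }
  if (any(abs(rowSums(cfg$composition) - 1) > 1e-9)) {
    stop("composition rows must sum to 1", call. = FALSE)
  }
  if (any(cfg$composition < 0)) stop("composition proportions must be >= 0", call. = FALSE)
  if (any(c(cfg$n_donors_per_group, cfg$sc_donors_per_group,
            cfg$cells_per_type_per_donor, cfg$markers_per_type) < 1L) ||
      cfg$nb_mean <= 0 || cfg$nb_dispersion <= 0 || cfg$bulk_intensity <= 0) {
    stop("counts, sizes and scale parameters must be positive", call. = FALSE)
  }
  if (cfg$bulk_noise_sd < 0 || cfg$covariate_effect_sd < 0) {
    stop("noise sds must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

# planted marker assignment: disjoint leading blocks of the gene vector
marker_map_from_config <- function(cfg) {
  genes <- gene_ids(cfg$n_genes)
  mpt <- cfg$markers_per_type
  out <- lapply(seq_along(cfg$cell_types), function(i) {
    genes[((i - 1L) * mpt + 1L):(i * mpt)]
  })
  names(out) <- cfg$cell_types
  out
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

# evaluate fn with a private RNG stream, restoring the caller's state
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- alpha  # degenerate underflow guard
  g / sum(g)
}

#' Simulate an annotated single-cell dataset with planted markers
#'
#' Draws negative-binomial counts per cell; a type's planted markers have
#' their NB mean inflated by `2^marker_log2fc` in cells of that type. Donors
#' belong to three groups (control and the two planted subsets) and each
#' donor's cells are allocated to types by a multinomial draw from the
#' group's composition vector, so subset-2 donors are ciliated-rich and
#' subset-1 donors myeloid-rich, as in the bulk cohorts.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `dataset` (an [sc_dataset()]) and `truth` (list with
#'   `marker_map`, `donor_group`, `composition`: realized per-donor cell-type
#'   fractions).
#' @export
simulate_single_cell <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, function() {
    types <- config$cell_types
    k <- length(types)
    total_per_donor <- config$cells_per_type_per_donor * k
    groups <- rep(names(config$sc_donors_per_group), config$sc_donors_per_group)
    donors <- sprintf("d%02d", seq_along(groups))
    names(groups) <- donors

    cell_type <- character(0); cell_donor <- character(0)
    for (d in seq_along(donors)) {
      p <- config$composition[groups[d], ]
      n_per_type <- as.vector(stats::rmultinom(1L, total_per_donor, p))
      cell_type <- c(cell_type, rep(types, n_per_type))
      cell_donor <- c(cell_donor, rep(donors[d], total_per_donor))
    }
    n_cells <- length(cell_type)
    genes <- gene_ids(config$n_genes)
    marker_map <- marker_map_from_config(config)

    mu <- matrix(config$nb_mean, nrow = config$n_genes, ncol = n_cells,
                 dimnames = list(genes, NULL))
    for (t in types) {
      mu[marker_map[[t]], cell_type == t] <- config$nb_mean * 2^config$marker_log2fc
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
                     nrow = config$n_genes,
                     dimnames = list(genes, sprintf("c%05d", seq_len(n_cells))))

    comp <- t(vapply(donors, function(d) {
      tab <- table(factor(cell_type[cell_donor == d], levels = types))
      as.vector(tab) / sum(tab)
    }, numeric(k)))
    colnames(comp) <- types

    list(
      dataset = sc_dataset(counts, cell_cluster = cell_type,
                           donor_id = cell_donor, donor_group = groups),
      truth = list(marker_map = marker_map, donor_group = groups,
                   composition = comp)
    )
  })
}

#' Simulate a bulk expression cohort with two planted patient subsets
#'
#' Each sample's expression is a composition mixture of per-type mean
#' profiles on the linear scale, log2-transformed, plus additive covariate
#' effects (smoking, gender) and Gaussian noise:
#' `log2(1 + sum_t p_t * profile_t) + X beta + eps`. Per-sample proportions
#' `p` are Dirichlet draws around the donor group's composition vector, so
#' subset 1 is myeloid-enriched and subset 2 ciliated/plasma-enriched and
#' T-depleted by construction.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `expr` (genes x samples matrix), `metadata` (tibble:
#'   `sample_id`, `diagnosis`, `subset`, `smoking`, `gender`) and `truth`
#'   (list with `marker_map`, `subset_labels`, `composition`).
#' @export
simulate_bulk_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, function() {
    types <- config$cell_types
    genes <- gene_ids(config$n_genes)
    marker_map <- marker_map_from_config(config)

    # per-type linear-scale mean profiles; non-markers identical across types
    profiles <- matrix(config$bulk_intensity, nrow = config$n_genes, ncol = length(types),
                       dimnames = list(genes, types))
    for (t in types) {
      profiles[marker_map[[t]], t] <- config$bulk_intensity * 2^config$marker_log2fc
    }

    groups <- rep(names(config$n_donors_per_group), config$n_donors_per_group)
    n <- length(groups)
    samples <- sprintf("s%03d", seq_len(n))

    comp <- t(vapply(groups, function(g) {
      rdirichlet1(config$dirichlet_concentration * config$composition[g, ])
    }, numeric(length(types))))
    rownames(comp) <- samples
    colnames(comp) <- types

    smoking <- rbinom(n, 1L, 0.5)
    gender <- rbinom(n, 1L, 0.5)
    n_cov <- max(1L, round(config$covariate_gene_fraction * config$n_genes))
    beta_smoke <- beta_gender <- numeric(config$n_genes)
    beta_smoke[sample.int(config$n_genes, n_cov)] <-
      rnorm(n_cov, 0, config$covariate_effect_sd)
    beta_gender[sample.int(config$n_genes, n_cov)] <-
      rnorm(n_cov, 0, config$covariate_effect_sd)

    base <- log2(1 + profiles %*% t(comp))  # genes x samples
    expr <- base +
      outer(beta_smoke, smoking) + outer(beta_gender, gender) +
      matrix(rnorm(config$n_genes * n, 0, config$bulk_noise_sd), nrow = config$n_genes)
    dimnames(expr) <- list(genes, samples)

    metadata <- tibble::tibble(
      sample_id = samples,
      diagnosis = ifelse(groups == "control", "control", "case"),
      subset = dplyr::case_when(groups == "subset1" ~ 1L,
                                groups == "subset2" ~ 2L,
                                TRUE ~ NA_integer_),
      smoking = smoking,
      gender = gender
    )
    list(expr = expr, metadata = metadata,
         truth = list(marker_map = marker_map,
                      subset_labels = setNames(groups, samples),
                      composition = comp))
  })
}

#' Simulate two replication cohorts sharing planted structure
#'
#' Both cohorts use the same marker map and group composition vectors but
#' independent donors, covariates and noise, emulating a discovery cohort
#' plus an independent replication cohort profiled separately.
#'
#' @param config a [sim_config()].
#' @param seed_a,seed_b seeds for the two cohorts.
#' @return list with elements `a` and `b`, each a [simulate_bulk_cohort()]
#'   result.
#' @export
simulate_replication_cohorts <- function(config, seed_a, seed_b) {
  list(a = simulate_bulk_cohort(config, seed = seed_a),
       b = simulate_bulk_cohort(config, seed = seed_b))
}
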