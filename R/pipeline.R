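#' Drug-response signature parameters
#'
#' @param lfc_cutoff minimum absolute log fold change (inclusive; default
#'   1.41).
#' @param p_cutoff maximum p-value (strict; default 0.05).
#' @param direction `"down"` keeps drug-downregulated genes (negative
#'   logfc), `"up"` the opposite.
#' @return list of class `drug_signature_params`.
#' @export
drug_signature_params <- function(lfc_cutoff = 1.41, p_cutoff = 0.05,
                                  direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(lfc_cutoff > 0, p_cutoff > 0)
  structure(list(lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff,
                 direction = direction),
            class = "drug_signature_params")
}

#' Combine drug-response gene tables into one signature
#'
#' Filters each table (columns `gene`, `logfc`, `p`) to
#' `|logfc| >= lfc_cutoff`, `p < p_cutoff` and the requested direction, and
#' returns the union of surviving genes as a named gene set. Mirrors the
#' construction of a drug-response signature from two experimental
#' compartments (e.g. whole-lung homogenate and isolated fibroblasts).
#'
#' @param table_a,table_b data frames with `gene`, `logfc`, `p` columns.
#' @param params a [drug_signature_params()].
#' @param name gene-set name.
#' @return character vector of gene ids with a `description` attribute.
#' @export
combine_drug_response_genes <- function(table_a, table_b,
                                        params = drug_signature_params(),
                                        name = "drug_response") {
  pick <- function(tb) {
    stopifnot(all(c("gene", "logfc", "p") %in% colnames(tb)))
    keep <- abs(tb$logfc) >= params$lfc_cutoff & tb$p < params$p_cutoff
    keep <- keep & if (params$direction == "down") tb$logfc < 0 else tb$logfc > 0
    tb$gene[keep]
  }
  genes <- union(pick(table_a), pick(table_b))
  if (!length(genes)) stop("no genes pass filters", call. = FALSE)
  structure(genes, description = sprintf("direction=%s", params$direction),
            name = name)
}

# default synthetic ligand-receptor pair table: one marker of each sender
# type paired with one marker of each other type, plus unpaired decoys
default_lr_table <- function(marker_map) {
  types <- names(marker_map)
  rows <- list()
  for (a in types) for (b in setdiff(types, a)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      ligand = marker_map[[a]][1L], receptor = marker_map[[b]][2L])
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

# synthetic drug-response input tables: ciliated and B/plasma markers are
# "downregulated by the drug" in each compartment, so the signature tracks
# the ciliated/plasma-enriched subset
default_drug_tables <- function(marker_map) {
  mk <- function(genes, lfc) tibble::tibble(gene = genes, logfc = lfc, p = 0.001)
  decoys <- tibble::tibble(gene = c("decoy1", "decoy2"),
                           logfc = c(-0.2, 2.0), p = c(0.001, 0.5))
  list(
    lung_homogenate = dplyr::bind_rows(mk(marker_map$ciliated, -2), decoys),
    both_compartments = dplyr::bind_rows(mk(marker_map$bcell_plasma, -1.8), decoys)
  )
}

#' Run the full stratification pipeline on a synthetic cohort
#'
#' Executes the whole analysis chain on simulated data with planted truth:
#' single-cell simulation, signature derivation, GSVA projection onto the
#' bulk cohort, consensus clustering of cases over the most variable genes
#' (with `k` forced to `force_k`), subset-vs-subset differential expression
#' with covariates, signature-score group tests, the ciliated-fraction donor
#' split with ligand-receptor scoring, a subset classifier on signature
#' scores, and drug-response signature scoring. Writes tabular outputs and
#' a JSON manifest to `out_dir` when given.
#'
#' @param config a [sim_config()]; all stage seeds derive from its seed.
#' @param out_dir optional output directory for TSV/GMT/JSON artifacts.
#' @param force_k number of consensus classes used downstream (default 2).
#' @param top_genes variable-gene count for clustering (default 5000,
#'   clamped to the gene count).
#' @param consensus a [consensus_params()].
#' @param signature a [signature_params()].
#' @param gsva a [gsva_params()].
#' @param lr an [lr_params()].
#' @param classifier a [classifier_spec()].
#' @param drug a [drug_signature_params()].
#' @return object of class `pipeline_result`: named list of stage outputs
#'   plus `manifest`.
#' @export
run_end_to_end <- function(config = sim_config(), out_dir = NULL,
                           force_k = 2L, top_genes = 5000L,
                           consensus = consensus_params(seed = config$seed),
                           signature = signature_params(),
                           gsva = gsva_params(),
                           lr = lr_params(seed = config$seed),
                           classifier = classifier_spec(seed = config$seed),
                           drug = drug_signature_params()) {
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  sc_sim <- simulate_single_cell(config, seed = config$seed)
  bulk <- simulate_bulk_cohort(config, seed = config$seed + 1L)
  note("simulate")

  sigs <- build_all_signatures(sc_sim$dataset, signature)
  note("signatures")

  scores <- gsva_scores(bulk$expr, as_gene_sets(sigs), gsva)
  note("gsva")

  case_ids <- bulk$metadata$sample_id[bulk$metadata$diagnosis == "case"]
  case_expr <- bulk$expr[, case_ids, drop = FALSE]
  cons <- consensus_cluster(
    select_top_variable_genes(case_expr, min(top_genes, nrow(case_expr))),
    consensus)
  labels <- consensus_labels(cons, force_k)
  note("consensus")

  meta <- dplyr::mutate(bulk$metadata,
                        consensus_class = dplyr::if_else(
                          .data$diagnosis == "case",
                          as.integer(labels[.data$sample_id]), NA_integer_))
  covars <- meta[match(case_ids, meta$sample_id), c("smoking", "gender")]
  de <- differential_expression(case_expr, labels[case_ids], covars)
  groups <- ifelse(meta$diagnosis == "control", "control",
                   paste0("class", meta$consensus_class))
  score_tests <- score_group_tests(scores, groups)
  note("subset_stats")

  pct <- celltype_percentages(sc_sim$dataset)
  split <- split_by_ciliated_fraction(pct, "ciliated", lr$ciliated_cutoff)
  lr_edges <- score_lr_interactions(sc_sim$dataset,
                                    default_lr_table(bulk$truth$marker_map), lr)
  lr_top <- if (nrow(lr_edges)) top_decile_filter(lr_edges, percentile = lr$top_percentile) else lr_edges
  note("ligand_receptor")

  cls <- fit_and_evaluate(t(scores[, case_ids, drop = FALSE]),
                          labels[case_ids], classifier)
  note("classification")

  drug_tabs <- default_drug_tables(bulk$truth$marker_map)
  drug_set <- combine_drug_response_genes(drug_tabs$lung_homogenate,
                                          drug_tabs$both_compartments, drug,
                                          name = "drug_response")
  drug_scores <- gsva_scores(bulk$expr, list(drug_response = drug_set), gsva)
  drug_test <- score_group_test(drug_scores["drug_response", ], groups)
  note("drug_signature")

  manifest <- list(
    seed = config$seed, force_k = force_k, top_genes = top_genes,
    stages = stages,
    n_samples = ncol(bulk$expr), n_genes = nrow(bulk$expr),
    n_signatures = length(sigs),
    consensus_seed = consensus$seed, lr_seed = lr$seed,
    classifier_seed = classifier$seed
  )

  result <- structure(
    list(sc = sc_sim, bulk = bulk, signatures = sigs, scores = scores,
         consensus = cons, subset_labels = labels, metadata = meta,
         de = de, score_tests = score_tests,
         ciliated_split = split, lr_interactions = lr_edges, lr_top = lr_top,
         classifier = cls, drug_set = drug_set, drug_scores = drug_scores,
         drug_test = drug_test, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, f) write.table(df, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  write_expression_table(result$bulk$expr, file.path(out_dir, "bulk_expression.tsv"))
  w(result$metadata, "metadata.tsv")
  write_gmt(as_gene_sets(result$signatures), file.path(out_dir, "signatures.gmt"))
  write_expression_table(result$scores, file.path(out_dir, "signature_scores.tsv"),
                         id_column = "signature")
  w(glance(result$consensus), "pac_scores.tsv")
  w(tibble::tibble(sample_id = names(result$subset_labels),
                   consensus_class = unname(result$subset_labels)),
    "consensus_labels.tsv")
  w(result$de, "differential_expression.tsv")
  w(result$score_tests, "score_group_tests.tsv")
  w(result$ciliated_split, "ciliated_split.tsv")
  if (nrow(result$lr_interactions)) w(result$lr_interactions, "lr_interactions.tsv")
  jsonlite::write_json(glance(result$classifier),
                       file.path(out_dir, "classifier_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_gmt(list(drug_response = result$drug_set),
            file.path(out_dir, "drug_signature.gmt"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d stages (%s)\n", length(x$manifest$stages),
              paste(x$manifest$stages, collapse = ", ")))
  invisible(x)
}
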