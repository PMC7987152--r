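#' Validate a bulk expression matrix
#'
#' A bulk expression matrix is an ordinary numeric matrix of normalized,
#' log-scale expression with genes in rows and samples in columns, identified
#' by unique `rownames` / `colnames`.
#'
#' @param m numeric matrix, genes x samples, with dimnames.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("expression matrix needs at least 2 genes and 2 samples", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values", call. = FALSE)
  invisible(m)
}

#' Read a bulk expression table
#'
#' Reads a TSV/CSV expression table with one header row of sample ids and a
#' first column of gene ids. Duplicate gene rows are collapsed by their mean
#' (the microarray probe convention) with a warning; duplicate sample columns
#' are an error.
#'
#' @param path file path; `.csv` is comma-separated, anything else tab.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"` for
#'   transposed files.
#' @return a validated genes x samples numeric matrix.
#' @export
read_expression_table <- function(path, orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs an id column plus data columns", call. = FALSE)
  ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]  # before data-frame subsetting de-duplicates them
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     col[bad[1L]], ids[bad[1L]], colnames(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(ids, sample_ids)
  if (orientation == "samples_in_rows") m <- t(m)
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids in expression table", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    dups <- unique(rownames(m)[duplicated(rownames(m))])
    warning(sprintf("collapsing %d duplicated gene id(s) by mean", length(dups)),
            call. = FALSE)
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(factor(rownames(m), levels = unique(rownames(m)))))
  }
  validate_expression_matrix(m)
  m
}

#' Write a bulk expression table
#'
#' @param m genes x samples numeric matrix.
#' @param path output path; `.csv` writes comma-separated, anything else tab.
#' @param id_column header for the gene id column.
#' @export
write_expression_table <- function(m, path, id_column = "gene_id") {
  validate_expression_matrix(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the most variable genes
#'
#' Keeps the `n` genes with the largest unbiased sample variance across
#' samples, the standard pre-filter before consensus clustering of bulk
#' cohorts. Ties are broken by gene id (lexicographic) so the selection is
#' deterministic.
#'
#' @param m genes x samples numeric matrix.
#' @param n number of genes to keep; if `n >= nrow(m)` the input is returned
#'   unchanged.
#' @return the row-subset matrix, ordered by decreasing variance.
#' @export
select_top_variable_genes <- function(m, n) {
  validate_expression_matrix(m)
  stopifnot(n >= 1L)
  if (n >= nrow(m)) return(m)
  v <- row_variances(m)
  ord <- order(-v, rownames(m))
  m[ord[seq_len(n)], , drop = FALSE]
}

# unbiased per-row variance without apply() overhead
row_variances <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}
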