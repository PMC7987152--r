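#' Construct a labelled single-cell counts dataset
#'
#' Bundles a genes x cells count matrix (dense or `Matrix` sparse) with the
#' per-cell annotations the pipeline needs: a cell-type/cluster label and a
#' donor label, plus an optional per-donor group (e.g. IPF vs control).
#'
#' @param counts genes x cells matrix of non-negative integer counts, with
#'   gene rownames and cell colnames.
#' @param cell_cluster character/factor of cluster labels, one per cell.
#' @param donor_id character/factor of donor labels, one per cell.
#' @param donor_group optional named character vector mapping donor id to a
#'   group label.
#' @return an object of class `sc_dataset`: a list with elements `counts`,
#'   `cell_cluster`, `donor_id`, `donor_group`.
#' @export
sc_dataset <- function(counts, cell_cluster, donor_id, donor_group = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids", call. = FALSE)
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else as.vector(counts)
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    stop("non-integer count: counts must be non-negative integers", call. = FALSE)
  }
  n <- ncol(counts)
  if (length(cell_cluster) != n || length(donor_id) != n) {
    stop("cell_cluster and donor_id must have one entry per cell", call. = FALSE)
  }
  if (anyNA(cell_cluster) || anyNA(donor_id)) {
    stop("every cell needs a cluster and a donor label", call. = FALSE)
  }
  structure(
    list(counts = counts,
         cell_cluster = as.character(cell_cluster),
         donor_id = as.character(donor_id),
         donor_group = donor_group),
    class = "sc_dataset"
  )
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d genes x %d cells, %d cell types, %d donors\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_cluster)), length(unique(x$donor_id))))
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$counts)

#' Read a Matrix Market single-cell dataset
#'
#' Reads the sparse-matrix layout emitted by common single-cell pipelines: a
#' coordinate MTX file with gene and cell id sidecars (one id per line), plus
#' a per-cell label table keyed by cell id. Cells absent from the label table
#' are dropped with a message.
#'
#' @param mtx_path coordinate Matrix Market file, genes x cells.
#' @param genes_path,cells_path one-column files of gene / cell ids, in
#'   matrix order.
#' @param labels_path tab-separated table with columns `cell_id`,
#'   `cell_cluster`, `donor_id` (extra columns ignored).
#' @return an [sc_dataset()].
#' @export
read_mtx_dataset <- function(mtx_path, genes_path, cells_path, labels_path) {
  counts <- Matrix::readMM(mtx_path)
  vals <- counts@x
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("non-integer count in MTX file", call. = FALSE)
  }
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  cells <- readLines(cells_path)
  cells <- cells[nzchar(cells)]
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells)) {
    stop(sprintf("MTX dimensions (%d x %d) disagree with sidecars (%d genes, %d cells)",
                 nrow(counts), ncol(counts), length(genes), length(cells)),
         call. = FALSE)
  }
  dimnames(counts) <- list(genes, cells)
  labels <- read.delim(labels_path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "cell_cluster", "donor_id")
  if (!all(needed %in% colnames(labels))) {
    stop("label table needs columns cell_id, cell_cluster, donor_id", call. = FALSE)
  }
  keep <- cells %in% labels$cell_id
  if (!all(keep)) {
    message(sprintf("dropping %d cell(s) without labels", sum(!keep)))
  }
  counts <- counts[, keep, drop = FALSE]
  idx <- match(colnames(counts), labels$cell_id)
  sc_dataset(counts,
             cell_cluster = labels$cell_cluster[idx],
             donor_id = labels$donor_id[idx])
}

#' Write an `sc_dataset` as MTX plus sidecars
#'
#' @param sc an [sc_dataset()].
#' @param dir output directory (created if missing); writes `counts.mtx`,
#'   `genes.tsv`, `cells.tsv`, `labels.tsv`.
#' @return the directory path, invisibly.
#' @export
write_mtx_dataset <- function(sc, dir) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(sc$counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  writeLines(rownames(sc$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(sc$counts), file.path(dir, "cells.tsv"))
  write.table(
    data.frame(cell_id = colnames(sc$counts),
               cell_cluster = sc$cell_cluster,
               donor_id = sc$donor_id,
               stringsAsFactors = FALSE),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Library-size log-normalize single-cell counts
#'
#' The usual counts-per-10k transform: `log2(1 + 1e4 * count / cell_total)`,
#' computed densely (signature work downstream operates gene-wise on the
#' whole matrix anyway).
#'
#' @param sc an [sc_dataset()].
#' @return dense genes x cells numeric matrix.
#' @export
lognormalize_counts <- function(sc) {
  stopifnot(inherits(sc, "sc_dataset"))
  m <- as.matrix(sc$counts)
  totals <- colSums(m)
  totals[totals == 0] <- 1
  log2(1 + sweep(m, 2L, totals, "/") * 1e4)
}
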