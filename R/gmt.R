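#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path GMT file path.
#' @return named list of gene sets; each element is a character vector of
#'   gene ids with attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) stop(sprintf("GMT line %d has duplicate genes", i), call. = FALSE)
    nms[i] <- parts[1L]
    sets[[i]] <- structure(genes, description = parts[2L])
  }
  names(sets) <- nms
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors (optionally carrying a
#'   `description` attribute; `"na"` is written when absent).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)) || length(sets) == 0L)
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(names(sets)[i], desc, as.character(sets[[i]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
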