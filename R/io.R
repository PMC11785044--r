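#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description and >=1 gene): ", substr(l, 1, 60))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  descriptions <- descriptions %||% names(sets)
  lines <- mapply(function(name, desc, genes) {
    paste(c(name, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write a count matrix as MatrixMarket with TSV sidecars
#'
#' Produces `matrix.mtx`, `genes.tsv` (gene_id, is_mito) and `barcodes.tsv`
#' (cell_id, line) under `dir`, the conventional droplet-data layout.
#'
#' @param counts a [count_matrix] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(counts$counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(gene_id = counts$gene_ids, is_mito = counts$mito_mask),
    file.path(dir, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = counts$cell_ids, line = counts$line_labels),
    file.path(dir, "barcodes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return a [count_matrix] object.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  cells <- utils::read.table(file.path(dir, "barcodes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  count_matrix(m, gene_ids = genes$gene_id, cell_ids = cells$cell_id,
               line_labels = cells$line,
               mito_mask = as.logical(genes$is_mito))
}

#' Write a drug-screen plate table as CSV
#'
#' @param plate a plate table as returned by [generate_plate()].
#' @param path output CSV path.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a drug-screen plate table from CSV
#'
#' @param path CSV with columns well, drug, dose, unit, replicate, is_control,
#'   atp_signal, size_day4, size_day6.
#' @return data.frame of class `plate_table`.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("well", "drug", "dose", "unit", "replicate", "is_control",
              "atp_signal", "size_day4", "size_day6")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("plate CSV missing columns: ", paste(missing, collapse = ", "))
  df$is_control <- as.logical(df$is_control)
  class(df) <- c("plate_table", "data.frame")
  df
}
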