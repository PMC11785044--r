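#' Construct a gene-by-cell count matrix container
#'
#' Bundles a non-negative integer UMI count matrix with gene ids, cell ids,
#' a per-cell sample-line label and a per-gene mitochondrial flag. This is
#' the input type of the QC stage.
#'
#' @param counts genes x cells matrix (base or Matrix) of non-negative counts.
#' @param gene_ids unique character gene identifiers (rows).
#' @param cell_ids unique character cell identifiers (columns).
#' @param line_labels character vector, one sample-line label per cell.
#' @param mito_mask logical vector, one flag per gene; defaults to genes whose
#'   id starts with `"mt-"` (the community naming convention).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids, cell_ids, line_labels,
                         mito_mask = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length must equal nrow(counts)")
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length must equal ncol(counts)")
  if (length(line_labels) != ncol(counts))
    stop("every cell needs a line label")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  mito_mask <- mito_mask %||% startsWith(gene_ids, "mt-")
  if (length(mito_mask) != nrow(counts))
    stop("mito_mask length must equal nrow(counts)")
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids),
         line_labels = as.character(line_labels),
         mito_mask = as.logical(mito_mask)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d line(s), %d mito gene(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$line_labels)), sum(x$mito_mask)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Subset a count_matrix by gene / cell index vectors, keeping metadata aligned.
subset_count_matrix <- function(x, genes = NULL, cells = NULL) {
  gi <- genes %||% seq_len(nrow(x$counts))
  ci <- cells %||% seq_len(ncol(x$counts))
  count_matrix(x$counts[gi, ci, drop = FALSE],
               gene_ids = x$gene_ids[gi], cell_ids = x$cell_ids[ci],
               line_labels = x$line_labels[ci], mito_mask = x$mito_mask[gi])
}
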