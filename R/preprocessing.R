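#' Quality-control parameters for cell and gene filtering
#'
#' Defaults are the conventional droplet QC thresholds for this kind of data:
#' cells need >= 500 UMIs, 200-8000 detected genes, novelty score
#' log10(genes)/log10(UMIs) > 0.80 and mitochondrial count fraction < 10%;
#' genes must be detected in more than 1/1000 of retained cells.
#'
#' @param min_umis minimum per-cell total UMIs (inclusive).
#' @param min_genes,max_genes detected-gene bounds per cell (inclusive).
#' @param min_log10_genes_per_umi novelty-score threshold (strict `>`).
#' @param max_mito_fraction mitochondrial count fraction bound (strict `<`).
#' @param min_cell_fraction_per_gene a gene is kept if detected in strictly
#'   more than this fraction of retained cells.
#' @param novelty_mode `"ratio_of_logs"` (default) computes
#'   log10(genes)/log10(UMIs); `"log_of_ratio"` computes the literal
#'   log10(genes/UMIs), which is always negative for UMI data and retains no
#'   cells at the default threshold.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_umis = 500, min_genes = 200, max_genes = 8000,
                      min_log10_genes_per_umi = 0.80,
                      max_mito_fraction = 0.10,
                      min_cell_fraction_per_gene = 0.001,
                      novelty_mode = c("ratio_of_logs", "log_of_ratio")) {
  if (min_genes > max_genes) stop_field("min_genes", "must be <= max_genes")
  check_fraction(max_mito_fraction, "max_mito_fraction")
  check_fraction(min_cell_fraction_per_gene, "min_cell_fraction_per_gene")
  structure(list(min_umis = min_umis, min_genes = min_genes,
                 max_genes = max_genes,
                 min_log10_genes_per_umi = min_log10_genes_per_umi,
                 max_mito_fraction = max_mito_fraction,
                 min_cell_fraction_per_gene = min_cell_fraction_per_gene,
                 novelty_mode = match.arg(novelty_mode)),
            class = "qc_params")
}

#' Filter cells and genes by quality-control rules
#'
#' Applies the five per-cell rules (total UMIs, detected-gene bounds, novelty
#' score, mitochondrial fraction), then removes genes detected in too few of
#' the retained cells. Boundary handling follows the stated thresholds
#' exactly: UMI and gene bounds are inclusive, novelty and mito bounds strict.
#'
#' @param counts a [count_matrix].
#' @param params a [qc_params()] list.
#' @return list with `counts` (filtered [count_matrix]), `report` (data.frame
#'   of per-rule removal counts; a cell failing several rules is counted under
#'   each) and `empty` (TRUE if no cell survived).
#' @export
qc_filter <- function(counts, params = qc_params()) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  umis <- Matrix::colSums(m)
  genes <- Matrix::colSums(m > 0)
  novelty <- switch(params$novelty_mode,
    ratio_of_logs = ifelse(umis > 1, log10(pmax(genes, 1)) / log10(umis), 0),
    log_of_ratio = log10(ifelse(umis > 0, genes / umis, NA)))
  mito_frac <- if (any(counts$mito_mask)) {
    Matrix::colSums(m[counts$mito_mask, , drop = FALSE]) / pmax(umis, 1)
  } else rep(0, ncol(m))

  pass_umi <- umis >= params$min_umis
  pass_gmin <- genes >= params$min_genes
  pass_gmax <- genes <= params$max_genes
  pass_nov <- novelty > params$min_log10_genes_per_umi
  pass_mito <- mito_frac < params$max_mito_fraction
  keep_cell <- pass_umi & pass_gmin & pass_gmax & pass_nov & pass_mito

  report <- data.frame(
    rule = c("min_umis", "min_genes", "max_genes", "novelty", "mito_fraction",
             "gene_detection"),
    removed = c(sum(!pass_umi), sum(!pass_gmin), sum(!pass_gmax),
                sum(!pass_nov), sum(!pass_mito), NA))

  if (!any(keep_cell)) {
    empty <- subset_count_matrix(counts, genes = integer(0), cells = integer(0))
    report$removed[6] <- nrow(m)
    return(list(counts = empty, report = report, empty = TRUE))
  }

  sub <- m[, keep_cell, drop = FALSE]
  det_frac <- Matrix::rowSums(sub > 0) / ncol(sub)
  keep_gene <- det_frac > params$min_cell_fraction_per_gene
  report$removed[6] <- sum(!keep_gene)

  list(counts = subset_count_matrix(counts, genes = which(keep_gene),
                                    cells = which(keep_cell)),
       report = report, empty = FALSE)
}

#' Normalize counts to log2(TPM+1)
#'
#' Each cell is scaled to one million total counts, then `log2(x + 1)` is
#' applied. For 3'-end UMI data there is no gene-length term, so TPM here is
#' counts-per-million; the conventional log2(TPM+1) name is kept.
#'
#' @param counts a [count_matrix].
#' @return object of class `expr_matrix`: dense genes x cells `values` matrix
#'   plus cell line labels.
#' @export
normalize_log_tpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  tot <- Matrix::colSums(counts$counts)
  if (any(tot == 0))
    stop("cell(s) with zero total counts: ",
         paste(counts$cell_ids[tot == 0], collapse = ", "))
  vals <- log2(sweep(as.matrix(counts$counts), 2, 1e6 / tot, "*") + 1)
  dimnames(vals) <- list(counts$gene_ids, counts$cell_ids)
  structure(list(values = vals, line_labels = counts$line_labels),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix (log2 TPM+1): %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Center expression per gene and clip negatives to zero
#'
#' Subtracts each gene's mean across cells, then sets every negative entry to
#' zero. The clipped matrix is the substrate for non-negative factorization;
#' per-gene means are stored so the centering is reversible.
#'
#' @param expr an `expr_matrix` from [normalize_log_tpm()].
#' @return object of class `centered_nonneg` with `values` (non-negative
#'   genes x cells matrix) and `gene_means`.
#' @export
center_and_clip <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(expr$values) == 0) stop("empty expression matrix")
  means <- rowMeans(expr$values)
  vals <- pmax(expr$values - means, 0)
  structure(list(values = vals, gene_means = means,
                 line_labels = expr$line_labels),
            class = "centered_nonneg")
}
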