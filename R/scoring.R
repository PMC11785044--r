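#' Build expression-matched background gene sets
#'
#' Bins all genes of the matrix into `n_bins` equal-frequency bins of mean
#' expression and, for each background set, replaces every query gene with a
#' random gene from its bin (drawn without replacement within a set whenever
#' the bin is large enough). The resulting sets match the query's
#' expression-level profile, which is what makes the per-cell score a
#' calibrated comparison.
#'
#' @param expr an `expr_matrix` (log2 TPM+1 values).
#' @param gene_set character vector of query genes, all present in `expr`.
#' @param n_sets number of background sets (default 1000).
#' @param n_bins number of equal-frequency expression bins (default 30).
#' @param seed integer seed.
#' @param gene_set_id optional label for the query set.
#' @return object of class `background_sets` with `sets` (list of gene
#'   vectors), the `bins` assignment used, `seed` and `gene_set_id`.
#' @export
build_background_sets <- function(expr, gene_set, n_sets = 1000L,
                                  n_bins = 30L, seed = 1L,
                                  gene_set_id = "query") {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- rownames(expr$values)
  missing <- setdiff(gene_set, genes)
  if (length(missing))
    stop("query genes absent from matrix: ", paste(missing, collapse = ", "))
  means <- rowMeans(expr$values)
  r <- rank(means, ties.method = "first")
  bins <- floor((r - 1) * n_bins / length(r)) + 1L
  names(bins) <- genes
  by_bin <- split(genes, bins)
  qbins <- bins[gene_set]
  need <- table(qbins)
  sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      unlist(lapply(names(need), function(b) {
        pool <- by_bin[[b]]
        n <- need[[b]]
        sample(pool, n, replace = n > length(pool))
      }), use.names = FALSE)
    })
  })
  structure(list(sets = sets, bins = bins, seed = as.integer(seed),
                 gene_set_id = gene_set_id, query = gene_set),
            class = "background_sets")
}

#' Score cells for a gene program against background sets
#'
#' For each cell, compares the mean per-gene-centered expression of the query
#' set with that of each background set. The p-value is the
#' pseudocount-corrected proportion of background sets expressed strictly
#' higher than the query, `p = (1 + exceedances) / (1 + n_sets)` (ties count
#' as not exceeding, and p = 0 is impossible). The raw score is `-log10(p)`;
#' the rescaled score maps the raw scores linearly to `[0, 1]` per program,
#' either across all cells (default) or within each line.
#'
#' @param expr the `expr_matrix` the backgrounds were built on.
#' @param gene_set the query gene set.
#' @param backgrounds a `background_sets` built on the same matrix.
#' @param rescale `"global"` (default) or `"per_line"`.
#' @return data.frame with cell_id, p, raw and rescaled columns.
#' @export
score_cells <- function(expr, gene_set, backgrounds,
                        rescale = c("global", "per_line")) {
  stopifnot(inherits(expr, "expr_matrix"),
            inherits(backgrounds, "background_sets"))
  rescale <- match.arg(rescale)
  genes <- rownames(expr$values)
  if (!all(gene_set %in% genes) ||
      !all(unlist(backgrounds$sets) %in% genes))
    stop("gene universe mismatch between matrix and background sets")
  centered <- expr$values - rowMeans(expr$values)
  qmean <- colMeans(centered[gene_set, , drop = FALSE])
  n_sets <- length(backgrounds$sets)
  # sparse averaging operator: one row per background set
  gi <- match(unlist(backgrounds$sets), genes)
  si <- rep(seq_len(n_sets), vapply(backgrounds$sets, length, 0L))
  len <- vapply(backgrounds$sets, length, 0L)
  S <- Matrix::sparseMatrix(i = si, j = gi, x = 1 / len[si],
                            dims = c(n_sets, length(genes)))
  bg <- as.matrix(S %*% centered)           # n_sets x cells
  exceed <- colSums(bg > rep(qmean, each = n_sets))
  p <- (1 + exceed) / (1 + n_sets)
  raw <- -log10(p)
  rescaled <- if (rescale == "global") {
    rng <- range(raw)
    if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else rep(0, length(raw))
  } else {
    out <- numeric(length(raw))
    for (l in unique(expr$line_labels)) {
      idx <- expr$line_labels == l
      rng <- range(raw[idx])
      out[idx] <- if (diff(rng) > 0) (raw[idx] - rng[1]) / diff(rng) else 0
    }
    out
  }
  data.frame(cell_id = colnames(expr$values), p = p, raw = raw,
             rescaled = rescaled, row.names = NULL)
}

#' Score cells for several gene programs
#'
#' Builds expression-matched backgrounds and scores every cell for each
#' program in `gene_sets`.
#'
#' @param expr an `expr_matrix`.
#' @param gene_sets named list of gene sets.
#' @param n_sets,n_bins,seed passed to [build_background_sets()]; each
#'   program uses a seed derived from `seed` and its name.
#' @param rescale passed to [score_cells()].
#' @return long data.frame (cell_id, program_id, p, raw, rescaled).
#' @export
score_programs <- function(expr, gene_sets, n_sets = 1000L, n_bins = 30L,
                           seed = 1L, rescale = "global") {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  out <- lapply(names(gene_sets), function(id) {
    bg <- build_background_sets(expr, gene_sets[[id]], n_sets = n_sets,
                                n_bins = n_bins,
                                seed = derive_seed(seed, id),
                                gene_set_id = id)
    sc <- score_cells(expr, gene_sets[[id]], bg, rescale = rescale)
    cbind(sc[, "cell_id", drop = FALSE], program_id = id,
          sc[, c("p", "raw", "rescaled")])
  })
  do.call(rbind, out)
}
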