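#' Combine datasets on shared genes with per-dataset centering
#'
#' Restricts every dataset to the shared gene set, mean-centers each dataset
#' per gene independently (so dataset-specific baseline offsets cancel), and
#' concatenates the cells with a dataset label.
#'
#' @param datasets named list of >= 2 `expr_matrix` objects (or plain
#'   genes x cells matrices with dimnames).
#' @return object of class `joint_dataset`: centered `values`, per-cell
#'   `dataset` labels, per-dataset pre-centering `gene_means` and cell
#'   counts.
#' @export
joint_center <- function(datasets) {
  stopifnot(length(datasets) >= 2)
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("dataset%d", seq_along(datasets))
  mats <- lapply(datasets, function(d)
    if (inherits(d, "expr_matrix")) d$values else as.matrix(d))
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) == 0) stop("datasets share no genes")
  mats <- lapply(mats, function(m) m[shared, , drop = FALSE])
  means <- vapply(mats, rowMeans, numeric(length(shared)))
  centered <- mapply(function(m, mu) m - mu, mats,
                     as.data.frame(means), SIMPLIFY = FALSE)
  values <- do.call(cbind, centered)
  labels <- rep(names(datasets), vapply(mats, ncol, 0L))
  structure(list(values = values, dataset = labels,
                 gene_means = means,
                 n_cells = vapply(mats, ncol, 0L)),
            class = "joint_dataset")
}

#' PCA of a joint dataset on its most expressed genes
#'
#' Selects the `top_genes` genes with the highest pre-centering mean
#' expression across the combined cells (centered means are zero by
#' construction, so the ranking uses the stored per-dataset means), then
#' computes principal-component scores for the cells.
#'
#' @param joint a `joint_dataset`.
#' @param top_genes number of genes to keep (default 4500); if the matrix has
#'   fewer, all are used and the result is flagged.
#' @param n_pcs number of components to return.
#' @return object of class `pc_selection`: `scores` (cells x n_pcs), the
#'   component standard deviations, `genes_used` and `all_genes_used` flag.
#' @export
joint_pca <- function(joint, top_genes = 4500L, n_pcs = 10L) {
  stopifnot(inherits(joint, "joint_dataset"))
  pooled_mean <- as.vector(joint$gene_means %*% joint$n_cells) /
    sum(joint$n_cells)
  short <- nrow(joint$values) < top_genes
  sel <- order(-pooled_mean)[seq_len(min(top_genes, nrow(joint$values)))]
  if (n_pcs > min(length(sel), ncol(joint$values)))
    stop(sprintf("n_pcs (%d) exceeds the matrix rank bound (%d)",
                 n_pcs, min(length(sel), ncol(joint$values))))
  pca <- stats::prcomp(t(joint$values[sel, , drop = FALSE]), center = TRUE,
                       scale. = FALSE, rank. = n_pcs)
  structure(list(scores = pca$x[, seq_len(n_pcs), drop = FALSE],
                 sdev = pca$sdev[seq_len(n_pcs)],
                 genes_used = rownames(joint$values)[sel],
                 all_genes_used = short,
                 dataset = joint$dataset),
            class = "pc_selection")
}

#' Select the PC pair most correlated with two program scores
#'
#' Correlates each of the leading components with the two target program
#' score vectors and returns the component pair (with its program
#' assignment) maximizing the minimum |r|, subject to both correlations
#' being strong (|r| strictly above `r_threshold`; anti-correlation
#' qualifies).
#'
#' @param pcs a `pc_selection`.
#' @param score1,score2 per-cell score vectors named by cell id for the two
#'   programs of interest.
#' @param r_threshold correlation magnitude threshold (default 0.35).
#' @param n_search number of leading components searched (default 10).
#' @return list with `status` (`"ok"` or `"none"`), the chosen `pair`,
#'   its per-program `r`, and the full `correlations` table.
#' @export
select_pc_pair <- function(pcs, score1, score2, r_threshold = 0.35,
                           n_search = 10L) {
  stopifnot(inherits(pcs, "pc_selection"))
  cells <- rownames(pcs$scores)
  common <- intersect(intersect(cells, names(score1)), names(score2))
  if (length(common) == 0) stop("no shared cells between scores and PCs")
  n_search <- min(n_search, ncol(pcs$scores))
  X <- pcs$scores[common, seq_len(n_search), drop = FALSE]
  ctab <- cbind(prog1 = stats::cor(X, score1[common])[, 1],
                prog2 = stats::cor(X, score2[common])[, 1])
  best <- NULL
  for (i in seq_len(n_search - 1)) for (j in (i + 1):n_search) {
    for (assign in list(c(i, j), c(j, i))) {
      r1 <- ctab[assign[1], "prog1"]; r2 <- ctab[assign[2], "prog2"]
      if (abs(r1) > r_threshold && abs(r2) > r_threshold) {
        val <- min(abs(r1), abs(r2))
        if (is.null(best) || val > best$value)
          best <- list(value = val, pair = assign, r = c(r1, r2))
      }
    }
  }
  if (is.null(best))
    return(list(status = "none", pair = NULL, r = NULL,
                correlations = ctab))
  list(status = "ok",
       pair = colnames(pcs$scores)[best$pair],
       r = stats::setNames(best$r, c("prog1", "prog2")),
       correlations = ctab)
}
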