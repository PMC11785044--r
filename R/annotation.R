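#' Similarity between a gene-program cluster and a reference meta-program
#'
#' Computes the mean Jaccard index between each constituent program's
#' top-gene list and the reference set, and the Pearson correlation between
#' the per-cell scores of the cluster and of the reference set.
#'
#' @param gp a `gp_cluster`.
#' @param mp_genes the reference meta-program gene set.
#' @param gp_scores,mp_scores numeric per-cell score vectors named by cell id
#'   (e.g. the `rescaled` column of [score_cells()]).
#' @return list with `mean_jaccard` and `correlation`.
#' @export
mp_similarity <- function(gp, mp_genes, gp_scores, mp_scores) {
  stopifnot(inherits(gp, "gp_cluster"))
  common <- intersect(names(gp_scores), names(mp_scores))
  if (length(common) == 0) stop("no common cells between score vectors")
  jac <- vapply(gp$members, function(p) jaccard_index(p$genes, mp_genes), 0)
  list(mean_jaccard = mean(jac),
       correlation = stats::cor(gp_scores[common], mp_scores[common]))
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing an overlap at least as large as
#' `|set_a intersect set_b|` when drawing `|set_b|` genes at random from a
#' universe of `universe_size` genes containing `|set_a|` marked genes.
#'
#' @param set_a,set_b character gene sets.
#' @param universe_size size of the gene universe.
#' @return upper-tail p-value.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe_size) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) > universe_size || length(b) > universe_size)
    stop("set larger than the universe")
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; a thin, named wrapper over
#' `p.adjust(method = "BH")` so the adjustment used throughout the annotation
#' stage is explicit.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Permutation confidence thresholds for GP-MP similarity
#'
#' Builds a pooled null for the mean Jaccard and score-correlation
#' statistics: in each permutation every constituent program's gene list is
#' replaced by a uniform random same-size draw from the gene universe (for
#' the Jaccard null), and one random signature-sized gene set per cluster is
#' scored against the matrix (for the correlation null). Null statistics are
#' pooled across all (cluster, reference, permutation) triples and the
#' threshold is the `confidence` quantile of each pool. Pooling is what
#' allows a 99.9% quantile to be estimated from 100 permutations.
#'
#' @param gps a `gp_clusters` object (or list of `gp_cluster`).
#' @param mps named list of reference meta-program gene sets.
#' @param expr the `expr_matrix` used for scoring.
#' @param mp_scores named list (per reference) of per-cell score vectors.
#' @param n_perm number of permutations (default 100).
#' @param confidence quantile of the pooled null (default 0.999).
#' @param n_background,n_bins background-set parameters used to score
#'   permuted sets.
#' @param seed integer seed.
#' @return list with `jaccard_threshold`, `correlation_threshold` and the
#'   pooled null draws.
#' @export
permutation_thresholds <- function(gps, mps, expr, mp_scores,
                                   n_perm = 100L, confidence = 0.999,
                                   n_background = 1000L, n_bins = 30L,
                                   seed = 1L) {
  clusters <- if (inherits(gps, "gp_clusters")) gps$clusters else gps
  stopifnot(n_perm >= 1, length(clusters) > 0, length(mps) > 0)
  universe <- rownames(expr$values)
  sizes <- lapply(clusters, function(cl)
    vapply(cl$members, function(p) length(p$genes), 0L))
  if (max(unlist(sizes)) > length(universe))
    stop("gene universe smaller than the largest program")
  null_jac <- numeric(0); null_cor <- numeric(0)
  for (perm in seq_len(n_perm)) {
    pseed <- derive_seed(seed, paste0("perm", perm))
    perm_lists <- with_seed(pseed, lapply(sizes, function(sz)
      lapply(sz, function(n) sample(universe, n))))
    for (ci in seq_along(clusters)) {
      sig_n <- max(length(clusters[[ci]]$signature), 1L)
      rand_sig <- with_seed(derive_seed(pseed, names(clusters)[ci] %||% "gp"),
                            sample(universe, min(sig_n, length(universe))))
      bg <- build_background_sets(expr, rand_sig, n_sets = n_background,
                                  n_bins = n_bins,
                                  seed = derive_seed(pseed, "bg"))
      rs <- score_cells(expr, rand_sig, bg)
      rand_scores <- stats::setNames(rs$rescaled, rs$cell_id)
      for (mi in seq_along(mps)) {
        jac <- vapply(perm_lists[[ci]], function(g)
          jaccard_index(g, mps[[mi]]), 0)
        null_jac <- c(null_jac, mean(jac))
        msc <- mp_scores[[mi]]
        common <- intersect(names(rand_scores), names(msc))
        null_cor <- c(null_cor, suppressWarnings(
          stats::cor(rand_scores[common], msc[common])))
      }
    }
  }
  nc <- null_cor[!is.na(null_cor)]  # constant score vectors yield NA
  list(jaccard_threshold = stats::quantile(null_jac, confidence, names = FALSE),
       correlation_threshold = if (length(nc))
         stats::quantile(nc, confidence, names = FALSE) else NA_real_,
       null_jaccard = null_jac, null_correlation = null_cor)
}

#' Annotate gene-program clusters against reference meta-programs
#'
#' For every (cluster, reference) pair computes the mean Jaccard and score
#' correlation, permutation confidence thresholds for both statistics, a
#' hypergeometric overlap test of the cluster signature against the
#' reference, and Benjamini-Hochberg q-values across all pairs. A pair is
#' flagged significant when both statistics exceed their permutation
#' thresholds.
#'
#' @param gps a `gp_clusters`.
#' @param mps named list of reference gene sets; genes absent from the matrix
#'   are dropped for scoring.
#' @param expr the `expr_matrix` the clusters were discovered on.
#' @param n_perm,confidence,n_background,n_bins,seed see
#'   [permutation_thresholds()].
#' @param universe_size hypergeometric universe; defaults to the number of
#'   genes in the matrix.
#' @return data.frame of class `mp_annotation` with one row per (GP, MP)
#'   pair.
#' @export
annotate_gps <- function(gps, mps, expr, n_perm = 100L, confidence = 0.999,
                         n_background = 1000L, n_bins = 30L, seed = 1L,
                         universe_size = NULL) {
  stopifnot(inherits(gps, "gp_clusters"))
  universe <- rownames(expr$values)
  universe_size <- universe_size %||% length(universe)
  mps_in <- lapply(mps, intersect, universe)
  if (any(!vapply(mps_in, length, 0L)))
    stop("reference set(s) with no genes in the matrix: ",
         paste(names(mps)[!vapply(mps_in, length, 0L)], collapse = ", "))
  gp_sets <- lapply(gps$clusters, `[[`, "signature")
  sc_gp <- score_programs(expr, gp_sets, n_sets = n_background,
                          n_bins = n_bins, seed = derive_seed(seed, "gp"))
  sc_mp <- score_programs(expr, mps_in, n_sets = n_background,
                          n_bins = n_bins, seed = derive_seed(seed, "mp"))
  vec <- function(df, id) {
    d <- df[df$program_id == id, ]
    stats::setNames(d$rescaled, d$cell_id)
  }
  mp_scores <- lapply(names(mps_in), function(m) vec(sc_mp, m))
  names(mp_scores) <- names(mps_in)
  thr <- permutation_thresholds(gps, mps_in, expr, mp_scores,
                                n_perm = n_perm, confidence = confidence,
                                n_background = n_background, n_bins = n_bins,
                                seed = derive_seed(seed, "perm"))
  rows <- list()
  for (g in names(gps$clusters)) {
    gvec <- vec(sc_gp, g)
    for (m in names(mps_in)) {
      sim <- mp_similarity(gps$clusters[[g]], mps_in[[m]], gvec,
                           mp_scores[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        gp_id = g, mp_id = m,
        mean_jaccard = sim$mean_jaccard,
        mean_correlation = sim$correlation,
        jaccard_threshold = thr$jaccard_threshold,
        correlation_threshold = thr$correlation_threshold,
        significant = isTRUE(sim$mean_jaccard > thr$jaccard_threshold &&
                               sim$correlation > thr$correlation_threshold),
        hypergeom_p = hypergeom_overlap(gps$clusters[[g]]$signature,
                                        mps_in[[m]], universe_size))
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_q <- fdr_adjust(out$hypergeom_p)
  class(out) <- c("mp_annotation", "data.frame")
  out
}

#' Per-gene detection frequency
#'
#' Fraction of sample lines (default) or of cells in which each gene is
#' detected (count > 0).
#'
#' @param counts a [count_matrix].
#' @param mode `"per_line"` or `"per_cell"`.
#' @return named numeric vector over genes.
#' @export
detection_frequency <- function(counts, mode = c("per_line", "per_cell")) {
  mode <- match.arg(mode)
  m <- counts$counts
  if (mode == "per_cell") {
    f <- Matrix::rowSums(m > 0) / ncol(m)
  } else {
    lines <- unique(counts$line_labels)
    det <- vapply(lines, function(l)
      Matrix::rowSums(m[, counts$line_labels == l, drop = FALSE] > 0) > 0,
      logical(nrow(m)))
    f <- rowMeans(det)
  }
  stats::setNames(f, counts$gene_ids)
}

#' Select representative secreted-program genes
#'
#' Two selection routes. Route A keeps program genes whose secretion
#' log2 fold-change exceeds 2 in at least one senescence condition of the
#' SASP table and whose detection frequency equals 1. Route B keeps program
#' genes overlapping any companion gene set (e.g. a related senescence
#' program from the same analysis or an external cohort). The result is the
#' union, with each gene tagged by route.
#'
#' @param gp_genes character vector of program genes.
#' @param sasp long data.frame with columns gene, condition, log2fc.
#' @param detection named per-gene detection-frequency vector (see
#'   [detection_frequency()]).
#' @param companion_sets list of companion gene sets.
#' @param log2fc_min fold-change threshold (strict `>`).
#' @return data.frame with columns gene and route
#'   (`"sasp"`, `"companion"` or `"both"`).
#' @export
select_representative_genes <- function(gp_genes, sasp, detection,
                                        companion_sets = list(),
                                        log2fc_min = 2) {
  stopifnot(all(c("gene", "condition", "log2fc") %in% names(sasp)))
  max_fc <- tapply(sasp$log2fc, sasp$gene, max, na.rm = TRUE)
  route_a <- gp_genes[gp_genes %in% names(max_fc)[max_fc > log2fc_min] &
                        gp_genes %in% names(detection)[detection >= 1]]
  route_b <- gp_genes[gp_genes %in% unique(unlist(companion_sets))]
  genes <- union(route_a, route_b)
  if (length(genes) == 0)
    return(data.frame(gene = character(0), route = character(0)))
  route <- ifelse(genes %in% route_a & genes %in% route_b, "both",
                  ifelse(genes %in% route_a, "sasp", "companion"))
  data.frame(gene = genes, route = route)
}
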