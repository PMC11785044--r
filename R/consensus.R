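#' Jaccard index of two gene sets
#'
#' @param a,b non-empty character vectors of gene ids.
#' @return |intersection| / |union|.
#' @export
jaccard_index <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("gene sets must be non-empty")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

# shared top-gene count between two programs
shared_genes <- function(p, q) length(intersect(p$genes, q$genes))

# scale an out-of-50 gene threshold when a program list is shorter than 50
scale_threshold <- function(thr, len_a, len_b, full = 50L) {
  m <- min(len_a, len_b)
  if (m >= full) thr else ceiling(thr / full * m)
}

#' Parameters of the consensus program-selection procedure
#'
#' Defaults encode the selection rules for top-50 programs: a program must
#' share at least 35/50 genes with a program of a different rank in the same
#' line, and at least 10/50 genes with a program in another line; during
#' greedy selection a program sharing strictly more than 10 genes with an
#' already selected same-line program is dropped as redundant; cluster
#' signature genes must appear in at least 40% of member programs.
#'
#' @param intra_line_overlap_min shared-gene minimum across ranks within a
#'   line (inclusive).
#' @param inter_line_overlap_min shared-gene minimum with any other line
#'   (inclusive).
#' @param redundancy_overlap_max redundancy bound in greedy selection
#'   (exclusive: sharing strictly more genes than this excludes).
#' @param signature_min_fraction fraction of member programs a signature gene
#'   must appear in (inclusive).
#' @param n_clusters number of program clusters to cut the UPGMA tree into.
#' @param rank_statistic inter-line similarity used to order greedy selection:
#'   maximum Jaccard to any other-line program (default) or the mean of
#'   per-other-line maxima.
#' @param require_inter_line if `FALSE`, the cross-line criterion is skipped
#'   (single-line collections would otherwise retain nothing).
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(intra_line_overlap_min = 35L,
                             inter_line_overlap_min = 10L,
                             redundancy_overlap_max = 10L,
                             signature_min_fraction = 0.40,
                             n_clusters = 7L,
                             rank_statistic = c("max", "mean_of_maxima"),
                             require_inter_line = TRUE) {
  stopifnot(intra_line_overlap_min > 0, inter_line_overlap_min > 0,
            redundancy_overlap_max > 0)
  if (signature_min_fraction <= 0 || signature_min_fraction > 1)
    stop_field("signature_min_fraction", "must be in (0, 1]")
  structure(list(intra_line_overlap_min = as.integer(intra_line_overlap_min),
                 inter_line_overlap_min = as.integer(inter_line_overlap_min),
                 redundancy_overlap_max = as.integer(redundancy_overlap_max),
                 signature_min_fraction = signature_min_fraction,
                 n_clusters = as.integer(n_clusters),
                 rank_statistic = match.arg(rank_statistic),
                 require_inter_line = isTRUE(require_inter_line)),
            class = "consensus_params")
}

#' Filter programs by cross-rank and cross-line robustness
#'
#' Retains programs that (1) share at least `intra_line_overlap_min` top genes
#' with a program of a *different* rank within the same line, and (2) share at
#' least `inter_line_overlap_min` top genes with a program in any *other*
#' line. Both criteria are evaluated against the full input collection.
#' Thresholds stated out of 50 are rescaled proportionally (ceiling) when a
#' compared list is shorter.
#'
#' @param collection a `program_collection` (normally spanning >= 2 lines).
#' @param params [consensus_params()].
#' @return the retained `program_collection`.
#' @export
robust_filter <- function(collection, params = consensus_params()) {
  if (length(collection) == 0) return(collection)
  lines <- vapply(collection, `[[`, "", "line_id")
  if (length(unique(lines)) < 2 && params$require_inter_line)
    warning("collection spans a single line; the cross-line criterion retains nothing")
  keep <- vapply(seq_along(collection), function(i) {
    p <- collection[[i]]
    crit1 <- FALSE; crit2 <- !params$require_inter_line
    for (j in seq_along(collection)) {
      if (j == i) next
      q <- collection[[j]]
      sh <- shared_genes(p, q)
      if (!crit1 && q$line_id == p$line_id && q$k != p$k &&
          sh >= scale_threshold(params$intra_line_overlap_min,
                                length(p$genes), length(q$genes)))
        crit1 <- TRUE
      if (!crit2 && q$line_id != p$line_id &&
          sh >= scale_threshold(params$inter_line_overlap_min,
                                length(p$genes), length(q$genes)))
        crit2 <- TRUE
      if (crit1 && crit2) break
    }
    crit1 && crit2
  }, TRUE)
  collection[keep]
}

# inter-line similarity used to rank programs for greedy selection
rank_statistic <- function(collection, params) {
  lines <- vapply(collection, `[[`, "", "line_id")
  vapply(seq_along(collection), function(i) {
    other <- which(lines != lines[i])
    if (!length(other)) return(0)
    jac <- vapply(other, function(j)
      jaccard_index(collection[[i]]$genes, collection[[j]]$genes), 0)
    if (params$rank_statistic == "max") max(jac)
    else mean(tapply(jac, lines[other], max))
  }, 0)
}

#' Greedy redundancy-removing program selection
#'
#' Ranks robust programs by their inter-line similarity (decreasing) and
#' scans the ranking, selecting each program unless an already selected
#' program from the same line shares strictly more than
#' `redundancy_overlap_max` top genes with it. Rank ties are broken by
#' (line id, rank k, component) ascending. The output preserves selection
#' order.
#'
#' @param robust a `program_collection` that already passed [robust_filter()].
#' @param params [consensus_params()].
#' @return the selected `program_collection`, in selection order.
#' @export
greedy_select <- function(robust, params = consensus_params()) {
  if (length(robust) == 0) return(robust)
  stat <- rank_statistic(robust, params)
  lines <- vapply(robust, `[[`, "", "line_id")
  ks <- vapply(robust, function(p) as.numeric(p[["k"]]), 0)
  comps <- vapply(robust, function(p) as.numeric(p[["component"]]), 0)
  ord <- order(-stat, lines, ks, comps)
  selected <- integer(0)
  for (i in ord) {
    redundant <- any(vapply(selected, function(s) {
      lines[s] == lines[i] &&
        shared_genes(robust[[s]], robust[[i]]) >
          scale_threshold(params$redundancy_overlap_max,
                          length(robust[[s]]$genes),
                          length(robust[[i]]$genes))
    }, TRUE))
    if (!redundant) selected <- c(selected, i)
  }
  robust[selected]
}

# pairwise Jaccard similarity matrix of a program collection
program_similarity <- function(collection) {
  n <- length(collection)
  J <- matrix(1, n, n, dimnames = list(names(collection), names(collection)))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      J[i, j] <- J[j, i] <-
        jaccard_index(collection[[i]]$genes, collection[[j]]$genes)
    }
  }
  J
}

#' Cluster selected programs by Jaccard similarity (UPGMA)
#'
#' Agglomerates programs with average linkage on distance 1 - Jaccard and
#' cuts the tree into `n_clusters` gene-program clusters; each cluster's
#' consensus signature is computed by [signature_genes()].
#'
#' @param selected a `program_collection` with >= 2 programs.
#' @param params [consensus_params()]; `n_clusters` must not exceed the
#'   program count.
#' @return object of class `gp_clusters`: list of cluster objects (`gp_id`,
#'   `members`, `signature`), plus the `hclust` tree and the similarity
#'   matrix.
#' @export
cluster_programs <- function(selected, params = consensus_params()) {
  if (length(selected) < 2) stop("need at least 2 programs to cluster")
  if (params$n_clusters > length(selected))
    stop(sprintf("n_clusters (%d) exceeds program count (%d)",
                 params$n_clusters, length(selected)))
  J <- program_similarity(selected)
  tree <- stats::hclust(stats::as.dist(1 - J), method = "average")
  assign <- stats::cutree(tree, k = params$n_clusters)
  clusters <- lapply(sort(unique(assign)), function(g) {
    members <- selected[which(assign == g)]
    structure(list(gp_id = sprintf("GP%d", g), members = members,
                   signature = signature_genes(
                     members, min_fraction = params$signature_min_fraction)),
              class = "gp_cluster")
  })
  names(clusters) <- vapply(clusters, `[[`, "", "gp_id")
  structure(list(clusters = clusters, tree = tree, similarity = J,
                 assignment = assign),
            class = "gp_clusters")
}

#' @export
print.gp_clusters <- function(x, ...) {
  cat(sprintf("gp_clusters: %d clusters over %d programs\n",
              length(x$clusters), length(x$assignment)))
  for (cl in x$clusters)
    cat(sprintf("  %s: %d member(s), %d signature gene(s)\n",
                cl$gp_id, length(cl$members), length(cl$signature)))
  invisible(x)
}

#' Consensus signature genes of a program cluster
#'
#' Genes present in at least `min_fraction` of the cluster's member programs
#' (count threshold `ceiling(min_fraction * n_members)`), ordered by
#' occurrence count (decreasing) then gene id.
#'
#' @param cluster a `gp_cluster`, or a list/`program_collection` of programs.
#' @param min_fraction membership fraction threshold (inclusive).
#' @return character vector of signature genes.
#' @export
signature_genes <- function(cluster, min_fraction = 0.40) {
  members <- if (inherits(cluster, "gp_cluster")) cluster$members else cluster
  if (length(members) == 0) stop("cluster has no member programs")
  tab <- table(unlist(lapply(members, `[[`, "genes")))
  thr <- ceiling(min_fraction * length(members))
  tab <- tab[tab >= thr]
  names(tab)[order(-tab, names(tab))]
}

#' Run the full consensus selection on a program collection
#'
#' Convenience wrapper: [robust_filter()], [greedy_select()], then
#' [cluster_programs()] (with `n_clusters` capped at the number of selected
#' programs).
#'
#' @param collection `program_collection` across lines.
#' @param params [consensus_params()].
#' @return list with `robust`, `selected` and `clusters` (a `gp_clusters`,
#'   or NULL if fewer than 2 programs were selected).
#' @export
consensus_programs <- function(collection, params = consensus_params()) {
  robust <- robust_filter(collection, params)
  selected <- greedy_select(robust, params)
  clusters <- NULL
  if (length(selected) >= 2) {
    p2 <- params
    p2$n_clusters <- min(params$n_clusters, length(selected))
    clusters <- cluster_programs(selected, p2)
  }
  list(robust = robust, selected = selected, clusters = clusters)
}
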