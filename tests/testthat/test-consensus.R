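test_that("Jaccard index follows set arithmetic and rejects empty sets", {
  g <- gene_pool(120)
  expect_equal(jaccard_index(g[1:50], g[1:50]), 1)
  expect_equal(jaccard_index(g[1:50], g[51:100]), 0)
  # 35 shared of two 50-gene sets: 35 / (50 + 50 - 35)
  expect_equal(jaccard_index(g[1:50], g[c(1:35, 71:85)]), 35 / 65)
  expect_error(jaccard_index(character(0), g[1:5]), "non-empty")
  # symmetry and bounds on random pairs
  set.seed(1)
  for (i in 1:20) {
    a <- sample(g, sample(5:50, 1)); b <- sample(g, sample(5:50, 1))
    expect_equal(jaccard_index(a, b), jaccard_index(b, a))
    expect_gte(jaccard_index(a, b), 0); expect_lte(jaccard_index(a, b), 1)
  }
})

test_that("robustness criteria accept at 35 intra-line and 10 inter-line shared genes", {
  g <- gene_pool(200)
  base <- g[1:50]
  mk <- function(line, k, comp, genes) make_program(line, k, comp, genes)
  # partner sharing exactly 35 genes at a different K, same line
  partner35 <- mk("line1", 7, 1, c(base[1:35], g[101:115]))
  partner34 <- mk("line1", 7, 1, c(base[1:34], g[101:116]))
  # other-line partner sharing exactly 10 / exactly 9 genes
  other10 <- mk("line2", 6, 1, c(base[1:10], g[121:160]))
  other9 <- mk("line2", 6, 1, c(base[1:9], g[121:161]))

  p <- mk("line1", 6, 1, base)
  keep <- robust_filter(program_collection(list(p, partner35, other10)))
  expect_true("line1_k6_c1" %in% names(keep))

  keep2 <- robust_filter(program_collection(list(p, partner34, other10)))
  expect_false("line1_k6_c1" %in% names(keep2))

  keep3 <- robust_filter(program_collection(list(p, partner35, other9)))
  expect_false("line1_k6_c1" %in% names(keep3))

  # same line, same K never satisfies the cross-rank criterion
  samek <- mk("line1", 6, 2, c(base[1:40], g[101:110]))
  keep4 <- robust_filter(program_collection(list(p, samek, other10)))
  expect_false("line1_k6_c1" %in% names(keep4))

  expect_length(robust_filter(program_collection(list())), 0)
  expect_warning(robust_filter(program_collection(list(p, partner35))),
                 "single line")
})

test_that("robust_filter is monotone in both thresholds", {
  set.seed(3)
  g <- gene_pool(150)
  progs <- list()
  for (l in c("line1", "line2")) for (k in c(6, 7)) for (cmp in 1:3)
    progs <- c(progs, list(make_program(l, k, cmp, sample(g, 50))))
  coll <- program_collection(progs)
  for (intra in c(5, 15, 25)) for (inter in c(5, 15)) {
    lo <- robust_filter(coll, consensus_params(intra, inter))
    hi_intra <- robust_filter(coll, consensus_params(intra + 10, inter))
    hi_inter <- robust_filter(coll, consensus_params(intra, inter + 10))
    expect_true(all(names(hi_intra) %in% names(lo)))
    expect_true(all(names(hi_inter) %in% names(lo)))
  }
})

test_that("greedy selection drops same-line programs sharing more than 10 genes", {
  g <- gene_pool(300)
  ref <- make_program("line2", 6, 1, g[1:50])
  top <- make_program("line1", 6, 1, g[1:50])       # rank 1: jaccard 1 to ref
  # shares 11 genes with `top`, weaker inter-line similarity
  redundant <- make_program("line1", 7, 1, c(g[1:11], g[101:139]))
  sel <- greedy_select(program_collection(list(top, redundant, ref)))
  expect_true("line1_k6_c1" %in% names(sel))
  expect_false("line1_k7_c1" %in% names(sel))

  # exactly 10 shared genes is NOT redundant (strict > rule)
  borderline <- make_program("line1", 7, 1, c(g[1:10], g[101:140]))
  sel2 <- greedy_select(program_collection(list(top, borderline, ref)))
  expect_true("line1_k7_c1" %in% names(sel2))

  single <- program_collection(list(make_program("line1", 6, 1, g[1:50])))
  expect_length(greedy_select(single), 1)
})

test_that("greedy selection matches an exhaustive simulation of the ordered scan", {
  # independent oracle: recompute the ranking and walk the scan with plain
  # loops, excluding any program sharing > 10 genes with an already chosen
  # program of the same line
  oracle <- function(progs) {
    lines <- vapply(progs, `[[`, "", "line_id")
    stat <- numeric(length(progs))
    for (i in seq_along(progs)) {
      best <- 0
      for (j in seq_along(progs)) {
        if (lines[j] == lines[i]) next
        inter <- length(intersect(progs[[i]]$genes, progs[[j]]$genes))
        uni <- length(union(progs[[i]]$genes, progs[[j]]$genes))
        best <- max(best, inter / uni)
      }
      stat[i] <- best
    }
    ks <- vapply(progs, `[[`, 0, "k")
    comps <- vapply(progs, `[[`, 0, "component")
    ord <- order(-stat, lines, ks, comps)
    chosen <- integer(0)
    for (i in ord) {
      ok <- TRUE
      for (s in chosen) {
        if (lines[s] == lines[i] &&
            length(intersect(progs[[s]]$genes, progs[[i]]$genes)) > 10)
          ok <- FALSE
      }
      if (ok) chosen <- c(chosen, i)
    }
    names(progs)[chosen]
  }
  set.seed(42)
  g <- gene_pool(120)
  for (trial in 1:25) {
    n <- sample(2:6, 1)
    lines <- sample(paste0("line", 1:3), n, replace = TRUE)
    progs <- lapply(seq_len(n), function(i)
      make_program(lines[i], sample(6:9, 1), i, sample(g, 50)))
    coll <- program_collection(progs)
    expect_equal(names(greedy_select(coll)), oracle(coll),
                 info = paste("trial", trial))
  }
})

test_that("UPGMA merge heights equal hand-computed average linkage", {
  g <- gene_pool(100)
  # pairwise Jaccard computed by set arithmetic:
  # A-B share 40 (J = 40/60), A-C share 10 (J = 10/90), B-C share 10
  A <- make_program("line1", 6, 1, g[1:50])
  B <- make_program("line2", 6, 1, c(g[1:40], g[51:60]))
  C <- make_program("line3", 6, 1, c(g[1:10], g[61:100]))
  cl <- cluster_programs(program_collection(list(A, B, C)),
                         consensus_params(n_clusters = 2))
  dAB <- 1 - 40 / 60
  dAC <- 1 - 10 / 90
  dBC <- 1 - 10 / 90
  expect_equal(cl$tree$height, c(dAB, (dAC + dBC) / 2))
  # A and B merge first, C stays apart at the 2-cluster cut
  expect_equal(cl$assignment[["line1_k6_c1"]], cl$assignment[["line2_k6_c1"]])
  expect_false(cl$assignment[["line3_k6_c1"]] == cl$assignment[["line1_k6_c1"]])
})

test_that("degenerate clusterings behave: identical programs merge, singletons split", {
  g <- gene_pool(60)
  A <- make_program("line1", 6, 1, g[1:50])
  B <- make_program("line2", 6, 1, g[1:50])
  C <- make_program("line3", 6, 1, g[c(1:5, 11:55)])
  cl <- cluster_programs(program_collection(list(A, B, C)),
                         consensus_params(n_clusters = 2))
  expect_equal(cl$tree$height[1], 0)
  expect_equal(cl$assignment[[1]], cl$assignment[[2]])

  cl3 <- cluster_programs(program_collection(list(A, B, C)),
                          consensus_params(n_clusters = 3))
  expect_length(unique(cl3$assignment), 3)
  expect_error(
    cluster_programs(program_collection(list(A, B)),
                     consensus_params(n_clusters = 3)),
    "exceeds")
})

test_that("signature genes require presence in at least 40% of members", {
  g <- gene_pool(120)
  # gene g001 in 2/5 members (40%, inclusive), gene g002 in 1/5 (excluded)
  members <- list(
    make_program("line1", 6, 1, c("g001", "g002", g[10:20])),
    make_program("line1", 7, 1, c("g001", g[10:20])),
    make_program("line2", 6, 1, g[10:21]),
    make_program("line2", 7, 1, g[10:21]),
    make_program("line3", 6, 1, g[10:21]))
  sig <- signature_genes(members, min_fraction = 0.40)
  expect_true("g001" %in% sig)
  expect_false("g002" %in% sig)
  # ordering: occurrence count decreasing, then gene id
  counts <- table(unlist(lapply(members, `[[`, "genes")))
  expect_equal(sig, names(counts)[order(-counts, names(counts))][
    seq_along(sig)])

  single <- list(make_program("line1", 6, 1, g[1:12]))
  expect_setequal(signature_genes(single), g[1:12])
})

test_that("planted shared programs survive the filter; line-specific ones fall to criterion 2", {
  cfg <- sim_config(n_lines = 3, cells_per_line = 200, n_genes = 1000,
                    library_size_range = c(4000, 8000),
                    programs = list(
                      program_spec(50, 0.3, 8),
                      program_spec(50, 0.3, 8, lines_present = 1)),
                    seed = 17)
  sim <- generate_counts(cfg)
  qc <- qc_filter(sim$counts, small_universe_qc())
  cen <- center_and_clip(normalize_log_tpm(qc$counts))
  progs <- list()
  for (l in unique(cen$line_labels)) {
    idx <- cen$line_labels == l
    progs <- c(progs, unclass(
      run_nmf_range(cen$values[, idx], ks = c(6, 7), seed = 1, line_id = l)))
  }
  robust <- robust_filter(program_collection(progs))
  j_shared <- vapply(robust, function(p)
    jaccard_index(p$genes, sim$truth$programs$program1), 0)
  j_spec <- vapply(robust, function(p)
    jaccard_index(p$genes, sim$truth$programs$program2), 0)
  expect_gte(max(j_shared), 0.5)   # shared program present
  expect_true(length(j_spec) == 0 || max(j_spec) < 0.5)
})
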