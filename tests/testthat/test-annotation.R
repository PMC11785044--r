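toy_cluster <- function(gene_lists, id = "GP1") {
  members <- lapply(seq_along(gene_lists), function(i)
    make_program(paste0("line", i), 6, i, gene_lists[[i]]))
  structure(list(gp_id = id,
                 members = members,
                 signature = signature_genes(members)),
            class = "gp_cluster")
}

test_that("GP-MP similarity covers the identity, null and mismatch cases", {
  g <- gene_pool(100)
  cells <- sprintf("c%02d", 1:30)
  s1 <- setNames(runif(30), cells)
  gp <- toy_cluster(list(g[1:50]))
  # single constituent equal to the reference: mean Jaccard 1, r = 1
  sim <- mp_similarity(gp, g[1:50], s1, s1)
  expect_equal(sim$mean_jaccard, 1)
  expect_equal(sim$correlation, 1)
  # disjoint sets, independent scores
  set.seed(2)
  s2 <- setNames(runif(30), cells)
  sim2 <- mp_similarity(gp, g[51:100], s1, s2)
  expect_equal(sim2$mean_jaccard, 0)
  expect_lt(abs(sim2$correlation), 0.5)
  expect_error(mp_similarity(gp, g[1:50], s1,
                             setNames(runif(5), paste0("x", 1:5))),
               "common cells")
})

test_that("hypergeometric overlap matches the closed form and exhaustive enumeration", {
  g <- gene_pool(100)
  # complete overlap of two 10-gene sets in a universe of 100
  expect_equal(hypergeom_overlap(g[1:10], g[1:10], 100),
               1 / choose(100, 10))
  # no overlap, small sets, large universe: p close to 1
  expect_gt(hypergeom_overlap(g[1:3], g[4:6], 1000), 0.97)
  expect_error(hypergeom_overlap(g[1:30], g[1:5], 20), "universe")

  # exhaustive oracle on universes <= 25: sum the tail of the density
  enum_p <- function(na, nb, k, N) {
    js <- k:min(na, nb)
    sum(choose(na, js) * choose(N - na, nb - js)) / choose(N, nb)
  }
  set.seed(7)
  for (trial in 1:30) {
    N <- sample(8:25, 1)
    u <- gene_pool(N)
    a <- sample(u, sample(2:min(6, N - 1), 1))
    b <- sample(u, sample(2:min(6, N - 1), 1))
    k <- length(intersect(a, b))
    expect_equal(hypergeom_overlap(a, b, N),
                 enum_p(length(a), length(b), k, N),
                 tolerance = 1e-12, info = paste("trial", trial))
  }
})

test_that("BH adjustment reproduces hand-computed q-values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(0.034), 0.034)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.84)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("a degenerate permutation null collapses the threshold onto the constant", {
  # universe identical to the reference set and programs spanning it:
  # every permuted draw equals the reference, so all null Jaccards are 1
  u <- gene_pool(12)
  v <- matrix(rexp(12 * 25), 12, 25,
              dimnames = list(u, sprintf("c%02d", 1:25)))
  expr <- structure(list(values = v, line_labels = rep("line1", 25)),
                    class = "expr_matrix")
  gp <- toy_cluster(list(u))
  msc <- setNames(runif(25), colnames(v))
  thr <- permutation_thresholds(list(GP1 = gp), list(MP1 = u), expr,
                                list(MP1 = msc), n_perm = 5,
                                n_background = 20, n_bins = 3, seed = 1)
  expect_equal(thr$jaccard_threshold, 1)
  expect_true(all(thr$null_jaccard == 1))

  thr2 <- permutation_thresholds(list(GP1 = gp), list(MP1 = u), expr,
                                 list(MP1 = msc), n_perm = 5,
                                 n_background = 20, n_bins = 3, seed = 1)
  expect_identical(thr, thr2)  # seeded determinism
})

test_that("permutation thresholds increase with the confidence level", {
  cfg <- sim_config(n_lines = 1, cells_per_line = 60, n_genes = 150, seed = 3)
  expr <- normalize_log_tpm(generate_counts(cfg)$counts)
  u <- rownames(expr$values)
  gp <- toy_cluster(list(u[1:30], u[10:39]))
  msc <- setNames(runif(60), colnames(expr$values))
  thr_lo <- permutation_thresholds(list(GP1 = gp), list(MP1 = u[1:30]), expr,
                                   list(MP1 = msc), n_perm = 10,
                                   confidence = 0.5, n_background = 20,
                                   seed = 5)
  thr_hi <- permutation_thresholds(list(GP1 = gp), list(MP1 = u[1:30]), expr,
                                   list(MP1 = msc), n_perm = 10,
                                   confidence = 0.999, n_background = 20,
                                   seed = 5)
  expect_gte(thr_hi$jaccard_threshold, thr_lo$jaccard_threshold)
  expect_gte(thr_hi$correlation_threshold, thr_lo$correlation_threshold)
})

test_that("a cluster planted to equal a reference is flagged; unrelated pairs are not", {
  cfg <- sim_config(n_lines = 1, cells_per_line = 150, n_genes = 250,
                    programs = list(program_spec(40, 0.4, 8)), seed = 9)
  sim <- generate_counts(cfg)
  expr <- normalize_log_tpm(sim$counts)
  planted <- sim$truth$programs$program1
  members <- list(make_program("line1", 6, 1, planted),
                  make_program("line1", 7, 1, planted))
  gps <- structure(list(
    clusters = list(GP1 = structure(
      list(gp_id = "GP1", members = members,
           signature = signature_genes(members)),
      class = "gp_cluster")),
    assignment = c(GP1 = 1L)), class = "gp_clusters")
  unrelated <- setdiff(rownames(expr$values), planted)[1:40]
  ann <- annotate_gps(gps, list(MPmatch = planted, MPother = unrelated),
                      expr, n_perm = 8, n_background = 100, seed = 2)
  expect_s3_class(ann, "data.frame")
  expect_true(ann$significant[ann$mp_id == "MPmatch"])
  expect_false(ann$significant[ann$mp_id == "MPother"])
  expect_lt(ann$hypergeom_p[ann$mp_id == "MPmatch"], 1e-10)
  expect_true(all(ann$fdr_q >= ann$hypergeom_p))
})

test_that("representative-gene selection honors both routes and their boundaries", {
  gp <- c("Anxa1", "Ecm1", "Il1rn", "Cxcl5", "Cxcl1", "Cldn4", "Dull1",
          "Dull2")
  sasp <- data.frame(
    gene = c("Anxa1", "Anxa1", "Ecm1", "Il1rn", "Cxcl5", "Dull1", "Dull2"),
    condition = c("Fibro RAS", "Fibro IR", "Fibro ATV", "Epi IR", "Ex IR",
                  "Fibro RAS", "Fibro RAS"),
    log2fc = c(2.5, 1.0, 3.1, 2.2, 4.0, 1.9, 2.6))
  detection <- c(Anxa1 = 1, Ecm1 = 1, Il1rn = 1, Cxcl5 = 1, Cxcl1 = 1,
                 Cldn4 = 1, Dull1 = 1, Dull2 = 0.6)
  companions <- list(episen = c("Cxcl1", "Cldn4"))
  out <- select_representative_genes(gp, sasp, detection, companions)
  expect_setequal(out$gene[out$route == "sasp"],
                  c("Anxa1", "Ecm1", "Il1rn", "Cxcl5"))
  expect_setequal(out$gene[out$route == "companion"], c("Cxcl1", "Cldn4"))
  # log2fc 1.9 in every condition: below the strict > 2 bound
  expect_false("Dull1" %in% out$gene)
  # fold-change passes but detection frequency below 1
  expect_false("Dull2" %in% out$gene)
})

test_that("detection frequency counts lines and cells as configured", {
  m <- matrix(0, 3, 4, dimnames = list(c("gA", "gB", "gC"),
                                       sprintf("c%d", 1:4)))
  m["gA", ] <- 1                    # everywhere
  m["gB", 1:2] <- 1                 # line1 only
  m["gC", c(1, 3)] <- c(1, 2)       # one cell in each line
  cm <- count_matrix(m, rownames(m), colnames(m),
                     line_labels = c("line1", "line1", "line2", "line2"))
  per_line <- detection_frequency(cm)
  expect_equal(unname(per_line), c(1, 0.5, 1))
  per_cell <- detection_frequency(cm, mode = "per_cell")
  expect_equal(unname(per_cell), c(1, 0.5, 0.5))
})
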