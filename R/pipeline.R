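# Stage orchestration: a single nested config drives simulate -> qc ->
# normalize -> nmf -> consensus -> score (-> annotate -> integrate), with
# per-stage seeds derived from the global seed and every artifact written to
# an output directory together with a manifest.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_lines = 3L, cells_per_line = 300L,
                    n_genes = 200L, mito_gene_fraction = 0.05,
                    baseline_logmean_mu = 0, baseline_logmean_sigma = 1,
                    library_size_range = c(2000, 6000), dispersion = 0.1,
                    programs = list()),
    input = list(counts_dir = NULL),
    qc = list(min_umis = 500, min_genes = 200, max_genes = 8000,
              min_log10_genes_per_umi = 0.80, max_mito_fraction = 0.10,
              min_cell_fraction_per_gene = 0.001,
              novelty_mode = "ratio_of_logs"),
    nmf = list(ks = 6:9, top_n = 50L, max_iter = 500L, tol = 1e-4),
    consensus = list(intra_line_overlap_min = 35L, inter_line_overlap_min = 10L,
                     redundancy_overlap_max = 10L,
                     signature_min_fraction = 0.40, n_clusters = 7L,
                     rank_statistic = "max"),
    score = list(n_background = 1000L, n_bins = 30L, rescale = "global"),
    annotate = list(enabled = FALSE, mps_gmt = NULL, n_perm = 100L,
                    confidence = 0.999),
    integrate = list(enabled = FALSE, top_genes = 4500L, n_pcs = 10L,
                     r_threshold = 0.35))
}

# merge user config into defaults, rejecting unknown keys by full path
merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]) && !(key %in% c("programs"))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Starts from the full default parameterization (QC 500/200/8000/0.80/10%/
#' 0.001, ranks 6-9, top-50 programs, 35/10/>10 overlap rules, 40% signature
#' fraction, 1,000 background sets, 100 permutations at 99.9% confidence,
#' 4,500 PCA genes, |r| > 0.35) and overrides it with the supplied nested
#' list. Unknown keys are rejected by name.
#'
#' @param overrides nested list mirroring the stage blocks (`seed`,
#'   `simulate`, `input`, `qc`, `nmf`, `consensus`, `score`, `annotate`,
#'   `integrate`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- merge_config(default_pipeline_config(), overrides)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full discovery pipeline
#'
#' Executes simulate (or load) -> qc -> normalize -> center/clip -> per-line
#' NMF across ranks -> consensus selection and clustering -> per-cell
#' program scoring, plus optional annotation against a reference GMT and
#' joint PCA across lines. Every stage consumes a seed derived
#' deterministically from the global seed and the stage name, writes its
#' artifacts under `out_dir`, and is recorded in `manifest.json`; reruns
#' with an identical config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, seed, files, params = NULL) {
    manifest$stages[[stage]] <<- list(seed = seed, files = files,
                                      params = params)
  }

  # --- simulate or load -----------------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    sseed <- derive_seed(config$seed, "simulate")
    sim_args <- config$simulate[setdiff(names(config$simulate), "enabled")]
    sim_args$programs <- lapply(sim_args$programs, function(p)
      if (inherits(p, "program_spec")) p else do.call(program_spec, p))
    cfg <- do.call(sim_config, c(sim_args, list(seed = sseed)))
    sim <- generate_counts(cfg)
    counts <- sim$counts
    write_counts_mtx(counts, file.path(out_dir, "counts"))
    files <- "counts/"
    if (length(sim$truth$programs)) {
      write_gmt(sim$truth$programs, file.path(out_dir, "truth_programs.gmt"))
      write_tsv(data.frame(
        program = rep(names(sim$truth$active_cells),
                      vapply(sim$truth$active_cells, length, 0L)),
        cell_id = unlist(sim$truth$active_cells, use.names = FALSE)),
        file.path(out_dir, "truth_cells.tsv"))
      files <- c(files, "truth_programs.gmt", "truth_cells.tsv")
    }
    note("simulate", sseed, files, config$simulate)
  } else {
    if (is.null(config$input$counts_dir))
      stop("stage 'input': counts_dir required when simulation is disabled")
    counts <- read_counts_mtx(config$input$counts_dir)
    sim <- NULL
    note("input", NA, config$input$counts_dir)
  }

  # --- qc + normalization ---------------------------------------------------
  qc <- qc_filter(counts, do.call(qc_params, config$qc))
  if (qc$empty) stop("stage 'qc': no cells survive filtering")
  write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))
  note("qc", NA, "qc_report.tsv", config$qc)
  expr <- normalize_log_tpm(qc$counts)
  centered <- center_and_clip(expr)
  note("normalize", NA, character(0))

  # --- per-line NMF ---------------------------------------------------------
  nseed <- derive_seed(config$seed, "nmf")
  lines <- unique(qc$counts$line_labels)
  progs <- list()
  for (l in lines) {
    idx <- centered$line_labels == l
    progs <- c(progs, unclass(run_nmf_range(
      centered$values[, idx, drop = FALSE], ks = config$nmf$ks,
      seed = nseed, top_n = config$nmf$top_n, line_id = l,
      max_iter = config$nmf$max_iter, tol = config$nmf$tol)))
  }
  collection <- program_collection(progs)
  write_gmt(lapply(collection, `[[`, "genes"),
            file.path(out_dir, "programs.gmt"))
  write_tsv(do.call(rbind, lapply(names(collection), function(id) {
    p <- collection[[id]]
    data.frame(program = id, gene = p$genes, coefficient = p$coefficients)
  })), file.path(out_dir, "program_coefficients.tsv"))
  note("nmf", nseed, c("programs.gmt", "program_coefficients.tsv"),
       config$nmf)

  # --- consensus ------------------------------------------------------------
  cpar <- do.call(consensus_params, config$consensus)
  cons <- consensus_programs(collection, cpar)
  if (length(cons$selected))
    write_gmt(lapply(cons$selected, `[[`, "genes"),
              file.path(out_dir, "selected_programs.gmt"))
  files <- "selected_programs.gmt"
  gp_sets <- NULL
  if (!is.null(cons$clusters)) {
    gp_sets <- lapply(cons$clusters$clusters, `[[`, "signature")
    gp_sets <- gp_sets[vapply(gp_sets, length, 0L) > 0]
    write_gmt(lapply(cons$clusters$clusters, `[[`, "signature")[
      names(gp_sets)], file.path(out_dir, "gp_signatures.gmt"))
    utils::write.table(cons$clusters$similarity,
                       file.path(out_dir, "program_similarity.tsv"),
                       sep = "\t", quote = FALSE)
    writeLines(ape::write.tree(ape::as.phylo(cons$clusters$tree)),
               file.path(out_dir, "program_tree.nwk"))
    files <- c(files, "gp_signatures.gmt", "program_similarity.tsv",
               "program_tree.nwk")
  }
  note("consensus", NA, files, config$consensus)

  # --- scoring --------------------------------------------------------------
  scores <- NULL
  if (!is.null(gp_sets) && length(gp_sets)) {
    scseed <- derive_seed(config$seed, "score")
    scores <- score_programs(expr, gp_sets,
                             n_sets = config$score$n_background,
                             n_bins = config$score$n_bins, seed = scseed,
                             rescale = config$score$rescale)
    write_tsv(scores, file.path(out_dir, "gp_scores.tsv"))
    note("score", scseed, "gp_scores.tsv", config$score)
  }

  # --- annotation (optional) ------------------------------------------------
  annotation <- NULL
  if (isTRUE(config$annotate$enabled) && !is.null(cons$clusters)) {
    aseed <- derive_seed(config$seed, "annotate")
    mps <- read_gmt(config$annotate$mps_gmt)
    annotation <- annotate_gps(cons$clusters, mps, expr,
                               n_perm = config$annotate$n_perm,
                               confidence = config$annotate$confidence,
                               n_background = config$score$n_background,
                               n_bins = config$score$n_bins, seed = aseed)
    write_tsv(annotation, file.path(out_dir, "gp_annotation.tsv"))
    note("annotate", aseed, "gp_annotation.tsv", config$annotate)
  }

  # --- integration (optional): treat each line as a dataset -----------------
  integration <- NULL
  if (isTRUE(config$integrate$enabled) && !is.null(scores) &&
      length(lines) >= 2 && length(gp_sets) >= 2) {
    per_line <- lapply(lines, function(l) {
      idx <- expr$line_labels == l
      structure(list(values = expr$values[, idx, drop = FALSE],
                     line_labels = expr$line_labels[idx]),
                class = "expr_matrix")
    })
    names(per_line) <- lines
    joint <- joint_center(per_line)
    pcs <- joint_pca(joint, top_genes = config$integrate$top_genes,
                     n_pcs = min(config$integrate$n_pcs,
                                 ncol(joint$values) - 1L,
                                 nrow(joint$values)))
    svec <- function(id) {
      d <- scores[scores$program_id == id, ]
      stats::setNames(d$rescaled, d$cell_id)
    }
    ids <- names(gp_sets)[1:2]
    integration <- select_pc_pair(pcs, svec(ids[1]), svec(ids[2]),
                                  r_threshold = config$integrate$r_threshold)
    write_tsv(data.frame(pc = rownames(integration$correlations),
                         integration$correlations),
              file.path(out_dir, "pc_correlations.tsv"))
    write_tsv(data.frame(cell_id = rownames(pcs$scores), pcs$scores),
              file.path(out_dir, "pc_scores.tsv"))
    note("integrate", NA, c("pc_correlations.tsv", "pc_scores.tsv"),
         config$integrate)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(counts = counts, sim = sim, qc = qc, expr = expr,
                 programs = collection, consensus = cons, scores = scores,
                 annotation = annotation, integration = integration,
                 manifest = manifest))
}
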