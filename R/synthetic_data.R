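#' Specification of one planted co-expression program
#'
#' Describes a gene program to plant in simulated counts: a set of genes whose
#' expected expression is multiplied by `effect_multiplier` in a fraction of
#' cells of the lines carrying the program.
#'
#' @param gene_count number of program genes (>= 10).
#' @param active_cell_fraction fraction of each carrying line's cells in which
#'   the program is active.
#' @param effect_multiplier fold-change applied to program-gene expected counts
#'   in active cells (> 1).
#' @param lines_present integer indices of the lines carrying the program;
#'   `NULL` means all lines.
#' @param rank_stable if `FALSE`, the program's effect is split across two
#'   half-strength gene subsets active in two partially overlapping cell
#'   subsets, so factorizations detect it inconsistently across ranks. This
#'   provides a true negative for cross-rank robustness filtering.
#' @return object of class `program_spec`.
#' @export
program_spec <- function(gene_count = 50, active_cell_fraction = 0.3,
                         effect_multiplier = 8, lines_present = NULL,
                         rank_stable = TRUE) {
  gene_count <- check_count(gene_count, "gene_count", min = 10L)
  check_fraction(active_cell_fraction, "active_cell_fraction")
  if (!is.numeric(effect_multiplier) || effect_multiplier <= 1)
    stop_field("effect_multiplier", "must be > 1")
  structure(list(gene_count = gene_count,
                 active_cell_fraction = active_cell_fraction,
                 effect_multiplier = effect_multiplier,
                 lines_present = lines_present,
                 rank_stable = isTRUE(rank_stable)),
            class = "program_spec")
}

#' Configuration for the synthetic single-cell count generator
#'
#' Defaults describe a compact three-line organoid-like dataset: lognormal
#' baseline gene abundances, uniform per-cell library sizes, negative-binomial
#' UMI noise, a small mitochondrial gene subset, and optional planted programs.
#'
#' @param n_lines number of sample lines.
#' @param cells_per_line cells simulated per line.
#' @param n_genes number of genes.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial (named
#'   with the conventional `mt-` prefix).
#' @param baseline_logmean_mu,baseline_logmean_sigma log-normal parameters for
#'   baseline relative gene abundances.
#' @param library_size_range length-2 interval of expected per-cell totals
#'   (UMIs), sampled uniformly.
#' @param dispersion negative-binomial overdispersion; `0` gives Poisson noise.
#' @param programs list of [program_spec()] objects.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 3, cells_per_line = 300, n_genes = 200,
                       mito_gene_fraction = 0.05,
                       baseline_logmean_mu = 0, baseline_logmean_sigma = 1,
                       library_size_range = c(2000, 6000),
                       dispersion = 0.1, programs = list(), seed = 1L) {
  n_lines <- check_count(n_lines, "n_lines")
  cells_per_line <- check_count(cells_per_line, "cells_per_line")
  n_genes <- check_count(n_genes, "n_genes", min = 10L)
  check_fraction(mito_gene_fraction, "mito_gene_fraction")
  if (!is.numeric(library_size_range) || length(library_size_range) != 2L ||
      any(library_size_range <= 0) || diff(library_size_range) < 0)
    stop_field("library_size_range", "must be an increasing positive interval")
  if (!is.numeric(dispersion) || dispersion < 0)
    stop_field("dispersion", "must be >= 0")
  if (!all(vapply(programs, inherits, TRUE, "program_spec")))
    stop_field("programs", "must be a list of program_spec objects")
  for (p in programs) {
    if (!is.null(p$lines_present) &&
        (any(p$lines_present < 1) || any(p$lines_present > n_lines)))
      stop_field("lines_present", "indexes a line outside 1..n_lines")
  }
  n_mito <- round(mito_gene_fraction * n_genes)
  need <- sum(vapply(programs, function(p) p$gene_count, 0L))
  if (need > n_genes - n_mito)
    stop_field("programs", "program gene sets do not fit among non-mito genes")
  structure(list(n_lines = n_lines, cells_per_line = cells_per_line,
                 n_genes = n_genes, mito_gene_fraction = mito_gene_fraction,
                 baseline_logmean_mu = baseline_logmean_mu,
                 baseline_logmean_sigma = baseline_logmean_sigma,
                 library_size_range = library_size_range,
                 dispersion = dispersion, programs = programs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate multi-line single-cell counts with planted gene programs
#'
#' Draws lognormal baseline gene abundances, uniform per-cell library sizes
#' and negative-binomial counts, then multiplies the expected counts of each
#' planted program's genes by its effect size in a fixed-size random subset of
#' cells of every line carrying the program. Mitochondrial genes are flagged
#' and excluded from program gene pools. Library sizes are not renormalized
#' after planting, so the active/inactive expected-count ratio of program
#' genes equals the configured multiplier.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix]) and `truth` (class
#'   `ground_truth`: per-program gene lists and active-cell ids).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_cells <- config$n_lines * config$cells_per_line
    gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
    n_mito <- round(config$mito_gene_fraction * config$n_genes)
    mito_idx <- if (n_mito > 0) sample(config$n_genes, n_mito) else integer(0)
    gene_ids[mito_idx] <- paste0("mt-", gene_ids[mito_idx])
    mito_mask <- seq_len(config$n_genes) %in% mito_idx

    line_labels <- rep(sprintf("line%d", seq_len(config$n_lines)),
                       each = config$cells_per_line)
    cell_ids <- sprintf("%s_c%04d", line_labels,
                        sequence(rep(config$cells_per_line, config$n_lines)))

    rel <- stats::rlnorm(config$n_genes, config$baseline_logmean_mu,
                         config$baseline_logmean_sigma)
    rel <- rel / sum(rel)
    lib <- stats::runif(n_cells, config$library_size_range[1],
                        config$library_size_range[2])
    mu <- outer(rel, lib)

    # assign disjoint program gene sets from the non-mito pool
    pool <- which(!mito_mask)
    truth_genes <- list(); truth_cells <- list()
    for (pi in seq_along(config$programs)) {
      p <- config$programs[[pi]]
      gsel <- sample(pool, p$gene_count)
      pool <- setdiff(pool, gsel)
      lines <- p$lines_present %||% seq_len(config$n_lines)
      n_active <- round(p$active_cell_fraction * config$cells_per_line)
      active <- integer(0)
      for (l in lines) {
        line_cells <- which(line_labels == sprintf("line%d", l))
        a1 <- sample(line_cells, n_active)
        if (p$rank_stable) {
          mu[gsel, a1] <- mu[gsel, a1] * p$effect_multiplier
          active <- c(active, a1)
        } else {
          half <- 1 + (p$effect_multiplier - 1) / 2
          a2 <- sample(line_cells, n_active)
          gA <- gsel[seq_len(floor(length(gsel) / 2))]
          gB <- setdiff(gsel, gA)
          mu[gA, a1] <- mu[gA, a1] * half
          mu[gB, a2] <- mu[gB, a2] * half
          active <- c(active, union(a1, a2))
        }
      }
      truth_genes[[sprintf("program%d", pi)]] <- gene_ids[gsel]
      truth_cells[[sprintf("program%d", pi)]] <- cell_ids[sort(active)]
    }

    vals <- if (config$dispersion > 0) {
      stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$dispersion)
    } else {
      stats::rpois(length(mu), as.vector(mu))
    }
    counts <- matrix(vals, nrow = config$n_genes)
    cm <- count_matrix(counts, gene_ids, cell_ids, line_labels, mito_mask)
    truth <- structure(list(programs = truth_genes, active_cells = truth_cells,
                            config = config),
                       class = "ground_truth")
    list(counts = cm, truth = truth)
  })
}

#' Build a drug-screen plate layout
#'
#' @param doses named list: drug name -> vector of doses.
#' @param n_replicates replicate wells per (drug, dose).
#' @param n_controls number of DMSO vehicle-control wells (>= 3).
#' @param unit dose unit label.
#' @return data.frame with one row per well.
#' @export
plate_layout <- function(doses, n_replicates = 3, n_controls = 6, unit = "uM") {
  stopifnot(length(doses) >= 1, !is.null(names(doses)))
  ctrl <- data.frame(drug = "DMSO", dose = 0, replicate = seq_len(n_controls),
                     is_control = TRUE)
  rows <- lapply(names(doses), function(d) {
    expand.grid(replicate = seq_len(n_replicates), dose = doses[[d]])[, 2:1]
  })
  drugs <- data.frame(drug = rep(names(doses),
                                 vapply(rows, nrow, 0L)),
                      do.call(rbind, rows), is_control = FALSE)
  out <- rbind(ctrl, drugs)
  out$unit <- unit
  out$well <- sprintf("W%03d", seq_len(nrow(out)))
  out[, c("well", "drug", "dose", "unit", "replicate", "is_control")]
}

#' Simulate a single-organoid drug-screen plate
#'
#' Control wells draw around the configured ATP baseline. Drug wells follow
#' the median-effect dose-response `fa = (D/Dm)^m / (1 + (D/Dm)^m)`, scaled by
#' the drug's maximum effect, with viability `1 - max_effect * fa`; organoid
#' growth from day 4 to day 6 is suppressed by the same factor. Gaussian noise
#' with standard deviation `noise_sd` (relative to each quantity's scale) is
#' added to signals and sizes.
#'
#' @param layout well layout from [plate_layout()] (or any data.frame with
#'   columns well, drug, dose, unit, replicate, is_control). At least 3
#'   control wells are required.
#' @param dose_response named list: drug -> `list(m=, Dm=, max_effect=)`
#'   (`max_effect` defaults to 1).
#' @param noise_sd relative Gaussian noise level; 0 gives a noiseless plate.
#' @param seed integer seed.
#' @param baseline mean control-well ATP signal.
#' @param size_day4 mean organoid size at day 4 (arbitrary area units).
#' @param control_growth day-6 / day-4 size ratio in control wells.
#' @return data.frame of class `plate_table` with atp_signal, size_day4 and
#'   size_day6 columns added to the layout.
#' @export
generate_plate <- function(layout, dose_response, noise_sd = 0, seed = 1L,
                           baseline = 1e6, size_day4 = 1000,
                           control_growth = 2) {
  if (sum(layout$is_control) < 3)
    stop("plate must contain at least 3 control wells")
  missing <- setdiff(unique(layout$drug[!layout$is_control]),
                     names(dose_response))
  if (length(missing))
    stop("no dose_response parameters for drug(s): ",
         paste(missing, collapse = ", "))
  with_seed(seed, {
    n <- nrow(layout)
    viability <- rep(1, n)
    for (i in which(!layout$is_control)) {
      dr <- dose_response[[layout$drug[i]]]
      max_effect <- dr$max_effect %||% 1
      fa <- (layout$dose[i] / dr$Dm)^dr$m /
        (1 + (layout$dose[i] / dr$Dm)^dr$m)
      viability[i] <- 1 - max_effect * fa
    }
    atp <- baseline * viability + stats::rnorm(n, 0, noise_sd * baseline)
    s4 <- size_day4 + stats::rnorm(n, 0, noise_sd * size_day4)
    s6 <- s4 * control_growth * viability *
      (1 + stats::rnorm(n, 0, noise_sd))
    out <- cbind(layout,
                 data.frame(atp_signal = atp, size_day4 = s4, size_day6 = s6))
    class(out) <- c("plate_table", "data.frame")
    out
  })
}
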