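# Shared fixture builders. Everything is generated in code at test time.

# a program object without running NMF
make_program <- function(line_id, k, component, genes) {
  structure(list(line_id = line_id, k = k, component = component,
                 genes = genes, coefficients = rev(seq_along(genes)),
                 short = length(genes) < 50),
            class = "program")
}

gene_pool <- function(n, prefix = "g") sprintf("%s%03d", prefix, seq_len(n))

# QC thresholds appropriate for a compact (few-hundred-gene) simulated
# universe: the novelty score scales with genome size, so the full-scale
# defaults are unsatisfiable on small universes.
small_universe_qc <- function() {
  qc_params(min_umis = 500, min_genes = 50, max_genes = 8000,
            min_log10_genes_per_umi = 0.5, max_mito_fraction = 1)
}

# hand-buildable count_matrix from a dense matrix
toy_counts <- function(m, lines = NULL, mito = NULL) {
  count_matrix(m,
               gene_ids = rownames(m) %||% gene_pool(nrow(m)),
               cell_ids = colnames(m) %||% sprintf("c%03d", seq_len(ncol(m))),
               line_labels = lines %||% rep("line1", ncol(m)),
               mito_mask = mito)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# median-effect curve evaluated directly from its parameters
predict_fa <- function(m, Dm, D) (D / Dm)^m / (1 + (D / Dm)^m)

# small hand-made plate table
toy_plate <- function(ctrl_atp, drug_atp, drug = "drugA",
                      ctrl_d4 = NULL, ctrl_d6 = NULL,
                      drug_d4 = NULL, drug_d6 = NULL) {
  n1 <- length(ctrl_atp); n2 <- length(drug_atp)
  df <- data.frame(
    well = sprintf("W%03d", seq_len(n1 + n2)),
    drug = c(rep("DMSO", n1), rep(drug, n2)),
    dose = c(rep(0, n1), rep(1, n2)),
    unit = "uM",
    replicate = c(seq_len(n1), seq_len(n2)),
    is_control = c(rep(TRUE, n1), rep(FALSE, n2)),
    atp_signal = c(ctrl_atp, drug_atp),
    size_day4 = c(ctrl_d4 %||% rep(100, n1), drug_d4 %||% rep(100, n2)),
    size_day6 = c(ctrl_d6 %||% rep(200, n1), drug_d6 %||% rep(200, n2)))
  class(df) <- c("plate_table", "data.frame")
  df
}
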