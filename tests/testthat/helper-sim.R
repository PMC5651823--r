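# Shared fixture configurations, kept small so the suite stays fast.

# Single-tissue, single-source, no-factor null configuration.
null_config <- function(n_genes = 500, n = 15, seed = 1, dispersion = 0.2) {
  simulation_config(
    n_genes = n_genes, n_tissues = 1,
    samples_per_condition = c(H = n, A = n, T = 2),
    dispersion = dispersion,
    libsize_by_source = list(src = c(meanlog = log(1e7), sdlog = 0.2)),
    n_unwanted_factors = 0, confound_strength = 0,
    n_housekeeping = 50,
    model_proportions = c(UD = 0), n_shared_tasa = 0,
    min_shared_tissues = 1, seed = seed)
}

# Small multi-tissue configuration with planted effects.
small_triad_config <- function(seed = 1, ...) {
  simulation_config(
    n_genes = 600, n_tissues = 3,
    samples_per_condition = c(H = 12, A = 12, T = 12),
    n_housekeeping = 60, n_shared_tasa = 8, min_shared_tissues = 2,
    seed = seed, ...)
}

# Tiny ExpressionMatrix built directly from a matrix.
toy_em <- function(values, condition = NULL, tissue = "t1",
                   scale = "counts") {
  if (is.null(condition)) condition <- rep("H", ncol(values))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  ExpressionMatrix(values,
                   data.frame(sample = colnames(values),
                              tissue = rep_len(tissue, ncol(values)),
                              condition = rep_len(condition, ncol(values)),
                              source = "src", subject = colnames(values)),
                   scale = scale)
}
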