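#' Default pipeline configuration
#'
#' Returns the full parameter set of \code{\link{run_pipeline}} with
#' defaults. Either \code{counts}/\code{metadata} paths or a
#' \code{simulate} block (arguments to \code{\link{simulation_config}})
#' must be supplied by the caller.
#'
#' @param ... overrides for any default; unknown keys are rejected.
#' @return named list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(...) {
  cf <- list(
    counts = NULL,            # path to gene x sample count TSV
    metadata = NULL,          # path to sample metadata TSV
    housekeeping = NULL,      # path to control-gene list (one id per line)
    gene_sets = NULL,         # optional GMT for preranked GSEA
    simulate = NULL,          # alternative: simulation_config() arguments
    out_dir = "nattriad_out",
    k = 1,                    # unwanted-variation factors per contrast
    p_cut = 0.05,             # Bonferroni gate
    lfc_cut = 1,              # |log2 fold-change| gate
    cpm_cut = 3,              # average log2 CPM gate
    prior_df = 30,            # dispersion shrinkage prior weight
    min_tissues = 3,          # sharing threshold for the TASA set
    ssgsea_alpha = 0.25,
    n_perm = 1000,            # preranked GSEA permutations
    score_p_cut = 0.001,      # Mann-Whitney corrected threshold
    seed = 1,
    verbose = TRUE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cf))
  if (length(unknown))
    stop("unknown pipeline configuration key(s): ",
         paste(unknown, collapse = ", "))
  cf[names(dots)] <- dots
  class(cf) <- "pipeline_config"
  cf
}

#' Read a pipeline configuration from a YAML file
#'
#' @param file YAML file whose top-level keys are
#'   \code{\link{pipeline_config}} arguments.
#' @return pipeline_config.
#' @export
read_pipeline_config <- function(file) {
  do.call(pipeline_config, yaml::read_yaml(file))
}

pipe_log <- function(cf, ...) if (isTRUE(cf$verbose)) message("[nattriad] ", ...)

#' Run the full triad analysis pipeline
#'
#' Sequences the stages: input (or simulation), abundance filtering,
#' per-tissue differential expression for the three contrasts (A:H, T:A,
#' T:H) with per-contrast upper-quartile normalization and control-gene
#' factor removal, nine-model classification, within-tissue model
#' enrichment, cross-tissue TASA sharing, TASA ssGSEA scoring with
#' Mann-Whitney group comparisons, two-reference deconvolution of NAT
#' samples, tumor-control comparison (T:H vs T:A), and cross-cohort
#' comparability checks. All stage outputs are written under
#' \code{out_dir} as TSV/JSON/GMT and a manifest records every parameter.
#'
#' @param config a \code{\link{pipeline_config}} (or path to a YAML file).
#' @return invisibly, a list with all in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- input ----
  truth <- NULL
  hk <- NULL
  if (!is.null(cf$simulate)) {
    sim_args <- cf$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cf$seed
    scf <- do.call(simulation_config, sim_args)
    if (!is.null(scf$min_shared_tissues) &&
        cf$min_tissues > scf$n_tissues)
      stop("min_tissues (", cf$min_tissues, ") exceeds the simulated ",
           "number of tissues (", scf$n_tissues, ")")
    pipe_log(cf, "simulating triad data (seed ", scf$seed, ")")
    sim <- simulate_triad(scf)
    raw <- sim$matrix
    truth <- sim$truth
    hk <- truth$housekeeping
    write_expression_tsv(raw, file.path(cf$out_dir, "counts.tsv"),
                         file.path(cf$out_dir, "metadata.tsv"))
    write_truth_json(truth, file.path(cf$out_dir, "truth.json"))
  } else {
    if (is.null(cf$counts) || is.null(cf$metadata))
      stop("either 'simulate' or both 'counts' and 'metadata' must be set")
    raw <- read_expression_tsv(cf$counts, cf$metadata)
    if (!is.null(cf$housekeeping)) hk <- read_gene_list(cf$housekeeping)
  }
  if (cf$k > 0 && is.null(hk))
    stop("k > 0 requires a housekeeping/control gene list")

  ## ---- preprocess ----
  filtered <- filter_low_abundance(raw)
  pipe_log(cf, nrow(filtered$values), " of ", nrow(raw$values),
           " genes pass the abundance filter")
  cpm <- uq_cpm(filtered)
  logcpm <- uq_cpm(filtered, log2 = TRUE)
  rle_tab <- rle_stats(logcpm)
  utils::write.table(rle_tab, file.path(cf$out_dir, "rle.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tissues <- unique(filtered$samples$tissue)

  ## ---- comparability ----
  panel <- build_reference(cpm)
  nat <- subset_em(cpm, samples = cpm$samples$condition == "A")
  assignment_tab <- assign_tissue(panel, nat)
  utils::write.table(assignment_tab,
                     file.path(cf$out_dir, "tissue_assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  concord <- NULL
  if (!is.null(hk)) {
    mH <- subset_em(logcpm, samples = logcpm$samples$condition == "H")
    mA <- subset_em(logcpm, samples = logcpm$samples$condition == "A")
    concord <- housekeeping_concordance(mH, mA, hk)
  }
  jsonlite::write_json(
    list(tissue_assignment_accuracy = attr(assignment_tab, "accuracy"),
         housekeeping = concord),
    file.path(cf$out_dir, "comparability.json"),
    auto_unbox = TRUE, digits = NA)

  ## ---- differential expression ----
  contrasts <- list(AH = c("H", "A"), TA = c("A", "T"), TH = c("H", "T"))
  de <- list()
  for (cn in names(contrasts)) {
    de[[cn]] <- lapply(stats::setNames(tissues, tissues), function(tt) {
      pipe_log(cf, "DE ", cn, " in ", tt)
      res <- de_contrast(filtered, tt, contrasts[[cn]], controls = hk,
                         k = cf$k, p_cut = cf$p_cut, lfc_cut = cf$lfc_cut,
                         cpm_cut = cf$cpm_cut, prior_df = cf$prior_df)
      write_de_tsv(res, file.path(cf$out_dir,
                                  sprintf("de_%s_%s.tsv", cn, tt)))
      res
    })
  }

  ## ---- nine models, enrichment, sharing, TASA ----
  models <- assign_models(de$AH, de$TA)
  utils::write.table(models, file.path(cf$out_dir, "models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enrich <- lapply(stats::setNames(tissues, tissues),
                   function(tt) model_enrichment(models, tt))
  sharing <- list(UD = sharing_summary(models, "UD",
                                       thresholds = 2:min(4, length(tissues))),
                  DU = sharing_summary(models, "DU",
                                       thresholds = 2:min(4, length(tissues))))
  jsonlite::write_json(list(model_enrichment = enrich, sharing = sharing),
                       file.path(cf$out_dir, "models_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  tasa <- shared_genes(models, "UD", cf$min_tissues)
  pipe_log(cf, length(tasa), " shared TASA genes (UD in >= ",
           cf$min_tissues, " tissues)")
  if (length(tasa))
    write_gmt(list(TASA_shared = tasa),
              file.path(cf$out_dir, "tasa_shared.gmt"))

  ## ---- TASA scoring ----
  tasa_scores <- NULL
  score_tests <- NULL
  if (length(tasa)) {
    tasa_scores <- ssgsea_score(cpm, tasa, alpha = cf$ssgsea_alpha)
    stab <- data.frame(sample = names(tasa_scores),
                       tissue = cpm$samples$tissue,
                       condition = cpm$samples$condition,
                       tasa_score = unname(tasa_scores))
    utils::write.table(stab, file.path(cf$out_dir, "tasa_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nc <- 2 * length(tissues)      # two comparisons per tissue
    score_tests <- do.call(rbind, lapply(tissues, function(tt) {
      idx <- stab$tissue == tt
      do.call(rbind, lapply(c("H", "T"), function(other) {
        sel <- idx & stab$condition %in% c("A", other)
        cmp <- compare_scores(stab$tasa_score[sel],
                              factor(stab$condition[sel],
                                     levels = c(other, "A")),
                              correction_factor = nc,
                              p_cut = cf$score_p_cut)
        cbind(tissue = tt, comparison = paste0("A_vs_", other), cmp)
      }))
    }))
    utils::write.table(score_tests,
                       file.path(cf$out_dir, "tasa_score_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- preranked GSEA (optional) ----
  gsea <- NULL
  if (!is.null(cf$gene_sets)) {
    sets <- read_gmt(cf$gene_sets)
    gsea <- lapply(stats::setNames(tissues, tissues), function(tt) {
      rk <- stats::setNames(de$AH[[tt]]$log2fc, de$AH[[tt]]$gene)
      preranked_gsea(rk, sets, n_perm = cf$n_perm, seed = cf$seed)
    })
    for (tt in tissues)
      utils::write.table(gsea[[tt]],
                         file.path(cf$out_dir,
                                   sprintf("gsea_AH_%s.tsv", tt)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- deconvolution ----
  deconv <- do.call(rbind, lapply(tissues, function(tt) {
    sig <- build_signature(cpm, tt)
    sub <- subset_em(cpm, samples = cpm$samples$tissue == tt)
    res <- deconvolve(sub, sig)
    cbind(tissue = tt,
          condition = sub$samples$condition[match(res$sample,
                                                  sub$samples$sample)],
          res)
  }))
  utils::write.table(deconv, file.path(cf$out_dir, "deconvolution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- control comparison ----
  control_cmp <- do.call(rbind, lapply(tissues, function(tt)
    cbind(tissue = tt, compare_controls(de$TH[[tt]], de$TA[[tt]]))))
  utils::write.table(control_cmp,
                     file.path(cf$out_dir, "control_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- manifest ----
  manifest <- list(
    package_version = as.character(utils::packageVersion("nattriad")),
    parameters = unclass(cf)[!vapply(cf, is.null, logical(1))],
    seed = cf$seed,
    n_genes_raw = nrow(raw$values),
    n_genes_filtered = nrow(filtered$values),
    tissues = tissues,
    n_tasa_shared = length(tasa),
    outputs = list.files(cf$out_dir))
  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(raw = raw, filtered = filtered, cpm = cpm,
                 logcpm = logcpm, rle = rle_tab, truth = truth,
                 panel = panel, tissue_assignment = assignment_tab,
                 housekeeping_concordance = concord, de = de,
                 models = models, model_enrichment = enrich,
                 sharing = sharing, tasa = tasa,
                 tasa_scores = tasa_scores, score_tests = score_tests,
                 gsea = gsea, deconvolution = deconv,
                 control_comparison = control_cmp, manifest = manifest))
}
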