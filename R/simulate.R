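#' Configuration for the triad simulator
#'
#' Describes a multi-tissue healthy / tumor-adjacent (NAT) / tumor count
#' simulation with known ground truth. Counts are negative-binomial with
#' per-gene dispersion (variance = mu + phi * mu^2). Per-gene, per-tissue
#' baselines are drawn uniformly on the log2 scale; condition effects are
#' planted on the log2-mean scale according to the nine expression models
#' (first letter: NAT vs healthy; second: tumor vs NAT; SS is the null
#' model and absorbs the unassigned remainder). Two source cohorts with
#' different library-size distributions emulate the integration of a
#' healthy-donor cohort with a tumor-project cohort; latent factors load on
#' every gene (including housekeeping genes, which carry no condition
#' effect) and may be partially confounded with the source cohort.
#'
#' For the gradient models (UU, DD) and the null model the NAT mean is a
#' per-sample convex mixture of the healthy and tumor log2 means (a
#' geometric mixture on the linear scale, since fold-change effects
#' compose multiplicatively); NAT-specific (UD, DU) and one-sided (US, DS,
#' SU, SD) models are planted directly so that their truth labels remain
#' exact.
#'
#' @param n_genes number of genes.
#' @param n_tissues number of tissue types.
#' @param samples_per_condition named vector/list (H, A, T) of per-tissue
#'   sample counts.
#' @param baseline_log_mean_range length-2 range of per-gene baseline log2
#'   means (roughly log2 CPM units).
#' @param dispersion scalar NB dispersion phi, or a length-2 range from
#'   which per-gene dispersions are drawn. Zero gives Poisson counts.
#' @param libsize_by_source named list mapping source cohort to
#'   \code{c(meanlog, sdlog)} of a log-normal library-size distribution.
#'   With two sources, healthy samples come from the first and NAT/tumor
#'   samples from the second; with one source all samples share it.
#' @param n_unwanted_factors number of latent unwanted-variation factors.
#' @param factor_sd standard deviation of factor scores across samples.
#' @param factor_loading_sd standard deviation of per-gene factor loadings
#'   (log2 units per score unit).
#' @param confound_strength mean shift of factor scores between the two
#'   source cohorts (0 = factors independent of source/condition).
#' @param n_housekeeping number of housekeeping genes (no condition effect
#'   in any tissue).
#' @param model_proportions named numeric of per-tissue gene fractions for
#'   the eight non-null models (names among SU, SD, US, DS, UU, DD, UD,
#'   DU); must sum to at most 1.
#' @param effect_log2fc scalar or length-2 range of planted per-contrast
#'   |log2 fold-change|.
#' @param effect_min_baseline minimum baseline log2 mean of genes eligible
#'   for planted effects, keeping planted signal in the detectable
#'   abundance regime.
#' @param n_shared_tasa number of genes planted as UD (TASA) in several
#'   tissues.
#' @param min_shared_tissues minimum number of tissues sharing each planted
#'   TASA gene (>= 2 when used with n_shared_tasa > 0).
#' @param mix_fraction_range sub-interval of [0, 1] from which each NAT
#'   sample's tumor-mixing fraction is drawn.
#' @param driver_effect strength with which the driver gene's tumor-side
#'   expression scales the subject's NAT-side TASA effects (matched-pairs
#'   simulation only).
#' @param seed integer seed; identical configurations give identical data.
#'
#' @return a validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_tissues = 4,
                              samples_per_condition = c(H = 30, A = 30, T = 30),
                              baseline_log_mean_range = c(3, 10),
                              dispersion = c(0.05, 0.5),
                              libsize_by_source = list(
                                healthy_cohort = c(meanlog = log(5e6), sdlog = 0.25),
                                tumor_cohort   = c(meanlog = log(2e7), sdlog = 0.25)),
                              n_unwanted_factors = 1,
                              factor_sd = 1,
                              factor_loading_sd = 0.3,
                              confound_strength = 0.5,
                              n_housekeeping = 100,
                              model_proportions = c(SU = 0.01, SD = 0.01,
                                                    US = 0.03, DS = 0.03,
                                                    UU = 0.02, DD = 0.02,
                                                    UD = 0.01, DU = 0.01),
                              effect_log2fc = c(1, 3),
                              effect_min_baseline = 5.5,
                              n_shared_tasa = 20,
                              min_shared_tissues = 3,
                              mix_fraction_range = c(0.35, 0.65),
                              driver_effect = 0,
                              seed = 1L) {
  cf <- list(n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
             samples_per_condition = unlist(samples_per_condition),
             baseline_log_mean_range = as.numeric(baseline_log_mean_range),
             dispersion = as.numeric(dispersion),
             libsize_by_source = libsize_by_source,
             n_unwanted_factors = as.integer(n_unwanted_factors),
             factor_sd = as.numeric(factor_sd),
             factor_loading_sd = as.numeric(factor_loading_sd),
             confound_strength = as.numeric(confound_strength),
             n_housekeeping = as.integer(n_housekeeping),
             model_proportions = model_proportions,
             effect_log2fc = as.numeric(effect_log2fc),
             effect_min_baseline = as.numeric(effect_min_baseline),
             n_shared_tasa = as.integer(n_shared_tasa),
             min_shared_tissues = as.integer(min_shared_tissues),
             mix_fraction_range = as.numeric(mix_fraction_range),
             driver_effect = as.numeric(driver_effect),
             seed = as.integer(seed))
  class(cf) <- "simulation_config"
  validate_simulation_config(cf)
  cf
}

NINE_MODELS <- c("SS", "SU", "SD", "US", "DS", "UU", "DD", "UD", "DU")

validate_simulation_config <- function(cf) {
  stopifnot(cf$n_genes > 0, cf$n_tissues > 0)
  spc <- cf$samples_per_condition
  if (!all(c("H", "A", "T") %in% names(spc)) || any(spc <= 0))
    stop("samples_per_condition must give a positive count for H, A and T")
  if (length(cf$baseline_log_mean_range) != 2 ||
      diff(cf$baseline_log_mean_range) < 0)
    stop("baseline_log_mean_range must be an increasing interval")
  if (any(cf$dispersion < 0)) stop("dispersion must be non-negative")
  if (!length(cf$libsize_by_source))
    stop("libsize_by_source must name at least one source cohort")
  mp <- cf$model_proportions
  if (length(mp)) {
    bad <- setdiff(names(mp), setdiff(NINE_MODELS, "SS"))
    if (length(bad))
      stop("unknown expression models in model_proportions: ",
           paste(bad, collapse = ", "))
    if (any(mp < 0))
      stop("model_proportions must be non-negative")
    if (sum(mp) > 1)
      stop("model_proportions sum to ", signif(sum(mp), 4),
           " > 1 (offending map: ",
           paste(names(mp), mp, sep = "=", collapse = ", "), ")")
  }
  if (any(cf$effect_log2fc <= 0)) stop("effect_log2fc must be positive")
  if (cf$n_shared_tasa > 0 && cf$min_shared_tissues > cf$n_tissues)
    stop("min_shared_tissues exceeds n_tissues")
  mfr <- cf$mix_fraction_range
  if (length(mfr) != 2 || mfr[1] < 0 || mfr[2] > 1 || mfr[1] > mfr[2])
    stop("mix_fraction_range must be a sub-interval of [0, 1]")
  if (cf$driver_effect < 0) stop("driver_effect must be non-negative")
  if (cf$n_housekeeping + cf$n_shared_tasa >= cf$n_genes)
    stop("housekeeping and shared TASA genes exhaust the gene universe")
  invisible(cf)
}

model_signs <- function(model) {
  s <- c(U = 1, D = -1, S = 0)
  cbind(ah = s[substr(model, 1, 1)], ta = s[substr(model, 2, 2)])
}

## Draw one tissue block of samples: metadata, library sizes, factor scores,
## NAT mixing fractions. Called inside the tissue-local RNG stream.
draw_tissue_samples <- function(cf, tissue) {
  spc <- cf$samples_per_condition
  cond <- rep(c("H", "A", "T"), times = spc[c("H", "A", "T")])
  n <- length(cond)
  ids <- sprintf("%s_%s%02d", tissue, cond, unlist(lapply(spc[c("H", "A", "T")], seq_len)))
  sources <- names(cf$libsize_by_source)
  src <- if (length(sources) == 1) rep(sources, n) else
    ifelse(cond == "H", sources[1], sources[2])
  lib <- vapply(src, function(s) {
    p <- cf$libsize_by_source[[s]]
    stats::rlnorm(1, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]])
  }, numeric(1))
  k <- cf$n_unwanted_factors
  scores <- matrix(stats::rnorm(n * k, sd = cf$factor_sd), n, k)
  if (k > 0 && length(sources) > 1) {
    ind <- as.numeric(src == sources[2])
    scores <- scores + cf$confound_strength * (ind - mean(ind))
  }
  rownames(scores) <- ids
  mix <- stats::runif(sum(cond == "A"), cf$mix_fraction_range[1],
                      cf$mix_fraction_range[2])
  names(mix) <- ids[cond == "A"]
  list(meta = data.frame(sample = ids, tissue = tissue, condition = cond,
                         source = src, subject = ids,
                         stringsAsFactors = FALSE),
       libsize = lib, scores = scores, mix = mix)
}

## Assign expression models to genes within one tissue.
## Returns a named character vector (gene -> model) of non-SS assignments.
assign_tissue_models <- function(cf, genes, baseline, hk, tasa_here) {
  assign <- character(0)
  if (length(tasa_here))
    assign <- stats::setNames(rep("UD", length(tasa_here)), tasa_here)
  mp <- cf$model_proportions
  eligible <- setdiff(genes[baseline >= cf$effect_min_baseline],
                      c(hk, names(assign)))
  for (m in names(mp)) {
    nm <- round(mp[[m]] * cf$n_genes)
    nm <- nm - if (m == "UD") length(tasa_here) else 0L
    if (nm <= 0) next
    if (nm > length(eligible))
      stop("not enough eligible genes above effect_min_baseline to plant ",
           "model ", m)
    pick <- sample(eligible, nm)
    eligible <- setdiff(eligible, pick)
    assign <- c(assign, stats::setNames(rep(m, nm), pick))
  }
  assign
}

## Per-gene log2 means for the three conditions in one tissue.
## Mixture models (SS, UU, DD) leave the NAT column NA: the NAT mean is
## formed per sample as a convex combination of the H and T linear means.
tissue_log2_means <- function(cf, genes, baseline, assign) {
  G <- length(genes)
  lmh <- baseline
  lma <- baseline
  lmt <- baseline
  mixed <- rep(TRUE, G)
  names(mixed) <- genes
  effects <- NULL
  if (length(assign)) {
    idx <- match(names(assign), genes)
    sg <- model_signs(assign)
    rfc <- function(n) if (length(cf$effect_log2fc) == 2)
      stats::runif(n, cf$effect_log2fc[1], cf$effect_log2fc[2])
    else rep(cf$effect_log2fc, n)
    d1 <- ifelse(sg[, "ah"] != 0, rfc(length(assign)), 0)
    d2 <- ifelse(sg[, "ta"] != 0, rfc(length(assign)), 0)
    lma[idx] <- baseline[idx] + sg[, "ah"] * d1
    lmt[idx] <- lma[idx] + sg[, "ta"] * d2
    mixed[idx] <- assign %in% c("UU", "DD")  # gradient models interpolate
    effects <- data.frame(gene = names(assign), model = unname(assign),
                          effect_ah = unname(sg[, "ah"] * d1),
                          effect_ta = unname(sg[, "ta"] * d2),
                          stringsAsFactors = FALSE)
  }
  list(H = lmh, A = lma, T = lmt, mixed = mixed, effects = effects)
}

## Expected linear (CPM-like) mean for every gene x sample in one tissue.
tissue_linear_means <- function(lm2, meta, mix, tasa_scale = NULL) {
  G <- length(lm2$H)
  base <- matrix(0, G, nrow(meta),
                 dimnames = list(names(lm2$H), meta$sample))
  for (j in seq_len(nrow(meta))) {
    cond <- meta$condition[j]
    if (cond == "H") {
      base[, j] <- 2^lm2$H
    } else if (cond == "T") {
      base[, j] <- 2^lm2$T
    } else {
      m <- mix[[meta$sample[j]]]
      la <- lm2$A
      if (!is.null(tasa_scale)) {
        ## matched-pairs driver coupling: rescale planted NAT-side effects
        sc <- tasa_scale[[meta$sample[j]]]
        la <- lm2$H + (lm2$A - lm2$H) * ifelse(lm2$mixed, 1, sc)
      }
      mu <- 2^la
      ## gradient genes interpolate H and T on the log2 scale: fold-change
      ## effects compose multiplicatively, and a symmetric interpolation
      ## keeps the planted U/D labels of both contrasts recoverable
      mix2 <- (1 - m) * lm2$H[lm2$mixed] + m * lm2$T[lm2$mixed]
      mu[lm2$mixed] <- 2^mix2
      base[, j] <- mu
    }
  }
  base
}

nb_draw <- function(mu, phi) {
  out <- mu
  pois <- phi == 0
  if (any(pois))
    out[pois, ] <- stats::rpois(sum(pois) * ncol(mu), mu[pois, ])
  if (any(!pois))
    out[!pois, ] <- stats::rnbinom(sum(!pois) * ncol(mu),
                                   mu = mu[!pois, ], size = 1 / phi[!pois])
  out
}

simulate_core <- function(cf, matched = FALSE) {
  set.seed(cf$seed)
  G <- cf$n_genes
  genes <- sprintf("g%05d", seq_len(G))
  hk <- sort(sample(genes, cf$n_housekeeping))
  ## housekeeping genes are stably expressed: one baseline for all tissues
  hk_baseline <- stats::runif(cf$n_housekeeping,
                              cf$baseline_log_mean_range[1],
                              cf$baseline_log_mean_range[2])
  phi <- if (length(cf$dispersion) == 2)
    stats::runif(G, cf$dispersion[1], cf$dispersion[2])
  else rep(cf$dispersion, G)
  names(phi) <- genes
  tissues <- sprintf("tissue%02d", seq_len(if (matched) 1L else cf$n_tissues))

  tasa <- character(0)
  tasa_tissues <- list()
  if (cf$n_shared_tasa > 0) {
    tasa <- sort(sample(setdiff(genes, hk), cf$n_shared_tasa))
    for (g in tasa) {
      nt <- if (matched) 1L else
        sample(seq(cf$min_shared_tissues, cf$n_tissues), 1)
      tasa_tissues[[g]] <- if (matched) tissues else sample(tissues, nt)
    }
  }

  k <- cf$n_unwanted_factors
  loadings <- matrix(stats::rnorm(G * k, sd = cf$factor_loading_sd), G, k,
                     dimnames = list(genes, if (k) paste0("W", seq_len(k))))
  tissue_seeds <- sample.int(.Machine$integer.max - 1L, length(tissues))

  counts <- NULL; meta <- NULL; scores <- NULL
  mix_all <- numeric(0); memb <- list(); eff <- list()
  driver <- NA_character_; driver_eff <- numeric(0)

  for (ti in seq_along(tissues)) {
    tissue <- tissues[ti]
    set.seed(tissue_seeds[ti])
    baseline <- stats::runif(G, cf$baseline_log_mean_range[1],
                             cf$baseline_log_mean_range[2])
    names(baseline) <- genes
    baseline[hk] <- hk_baseline
    tasa_here <- names(Filter(function(tt) tissue %in% tt, tasa_tissues))
    if (length(tasa_here)) {
      lo <- max(cf$effect_min_baseline, cf$baseline_log_mean_range[1])
      baseline[tasa_here] <- stats::runif(length(tasa_here), lo,
                                          cf$baseline_log_mean_range[2])
    }
    assign <- assign_tissue_models(cf, genes, baseline, hk, tasa_here)
    lm2 <- tissue_log2_means(cf, genes, baseline, assign)
    blk <- draw_tissue_samples(cf, tissue)

    tasa_scale <- NULL
    if (matched) {
      nA <- sum(blk$meta$condition == "A")
      ## matched subjects: pair each NAT sample with a tumor sample
      if (sum(blk$meta$condition == "T") != nA)
        stop("matched-pairs simulation requires equal A and T sample counts")
      aid <- blk$meta$sample[blk$meta$condition == "A"]
      tid <- blk$meta$sample[blk$meta$condition == "T"]
      subj <- sprintf("subj%03d", seq_len(nA))
      blk$meta$subject[match(aid, blk$meta$sample)] <- subj
      blk$meta$subject[match(tid, blk$meta$sample)] <- subj
      z <- stats::rnorm(nA)
      pool <- setdiff(genes[baseline >= cf$effect_min_baseline],
                      c(hk, names(assign)))
      driver <- sample(pool, 1)
      sc <- pmax(0, 1 + cf$driver_effect * z)
      tasa_scale <- stats::setNames(as.list(sc), aid)
      driver_eff <- stats::setNames(sc, aid)
      driver_z <- stats::setNames(z, tid)
    }

    mu <- tissue_linear_means(lm2, blk$meta, as.list(blk$mix), tasa_scale)
    colnames(mu) <- blk$meta$sample
    if (matched) {
      ## driver gene varies across subjects on the tumor side
      tj <- match(names(driver_z), colnames(mu))
      mu[driver, tj] <- mu[driver, tj] * 2^driver_z
    }
    if (k > 0)
      mu <- mu * 2^(loadings %*% t(blk$scores))
    offs <- blk$libsize / 1e6
    mu <- sweep(mu, 2, offs, `*`)
    cnt <- nb_draw(mu, phi)
    dimnames(cnt) <- list(genes, blk$meta$sample)
    storage.mode(cnt) <- "double"

    counts <- cbind(counts, cnt)
    meta <- rbind(meta, blk$meta)
    scores <- rbind(scores, blk$scores)
    mix_all <- c(mix_all, blk$mix)
    if (length(assign))
      memb[[tissue]] <- data.frame(tissue = tissue, gene = names(assign),
                                   model = unname(assign),
                                   stringsAsFactors = FALSE)
    if (!is.null(lm2$effects))
      eff[[tissue]] <- cbind(tissue = tissue, lm2$effects)
  }

  em <- ExpressionMatrix(counts, meta, scale = "counts")
  truth <- structure(list(
    deg_membership = if (length(memb)) do.call(rbind, memb) else
      data.frame(tissue = character(0), gene = character(0),
                 model = character(0)),
    effects = if (length(eff)) do.call(rbind, eff) else NULL,
    tasa_shared = tasa, tasa_tissues = tasa_tissues,
    mixing_fraction = mix_all,
    factor_scores = scores, factor_loadings = loadings,
    housekeeping = hk, dispersion = phi,
    driver_gene = driver, driver_effects = driver_eff),
    class = "SyntheticTruth")
  list(matrix = em, truth = truth)
}

#' Simulate a multi-tissue healthy/NAT/tumor count dataset
#'
#' Draws negative-binomial counts for every tissue in the configuration,
#' with planted differential-expression effects distributed over the nine
#' expression models, housekeeping genes free of condition effects, shared
#' TASA (UD) genes planted in several tissues, per-sample NAT mixing
#' fractions for the gradient models, latent unwanted-variation factors and
#' cohort-specific library sizes. The full set of planted parameters is
#' returned alongside the counts.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{matrix} (an
#'   \code{\link{ExpressionMatrix}} on the counts scale) and \code{truth}
#'   (a \code{SyntheticTruth} list recording planted model memberships,
#'   effect sizes, shared TASA genes, mixing fractions, factor scores and
#'   loadings, housekeeping genes and per-gene dispersions).
#' @export
simulate_triad <- function(config) {
  validate_simulation_config(config)
  simulate_core(config, matched = FALSE)
}

#' Simulate subject-matched NAT and tumor samples with a planted driver
#'
#' Single-tissue variant in which every NAT sample is paired with a tumor
#' sample from the same subject. All shared TASA genes are planted as UD in
#' this tissue, and one well-expressed null gene is designated the driver:
#' its tumor-side log2 expression varies across subjects, and each
#' subject's NAT-side TASA effect sizes are scaled by
#' \code{max(0, 1 + driver_effect * z)} where \code{z} is the subject's
#' driver deviation. With \code{driver_effect = 0} the tumor driver level
#' carries no information about the NAT TASA signature.
#'
#' @param config a \code{\link{simulation_config}}; \code{A} and \code{T}
#'   sample counts must be equal (the number of subjects).
#' @return as \code{\link{simulate_triad}}; \code{truth$driver_gene} and
#'   \code{truth$driver_effects} record the plant.
#' @export
simulate_matched_pairs <- function(config) {
  validate_simulation_config(config)
  simulate_core(config, matched = TRUE)
}

#' Write a SyntheticTruth record as JSON
#'
#' @param truth SyntheticTruth from a simulation.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
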