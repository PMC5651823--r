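#' Estimate per-gene NB dispersions by shrunken method of moments
#'
#' Counts are scaled to a common effective library size (upper-quartile
#' adjusted), the moment estimator \code{(variance - mean) / mean^2} is
#' computed within each group and pooled, floored at zero, and shrunk
#' toward the trimmed mean of all per-gene estimates with a configurable
#' prior weight expressed as prior degrees of freedom; strong
#' moderation keeps the Bonferroni-gated calls family-wise calibrated.
#'
#' @param m ExpressionMatrix on the counts scale.
#' @param groups factor (or coercible) of length \code{ncol(m$values)}
#'   with at least one level of size >= 2 per group.
#' @param prior_df prior degrees of freedom for shrinkage toward the
#'   trimmed mean (default 30).
#' @param trim trim fraction for the global mean (default 0.1).
#' @return named numeric vector of dispersions, one per gene, all >= 0.
#' @export
estimate_dispersion <- function(m, groups, prior_df = 30, trim = 0.1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "counts")
    stop("estimate_dispersion requires the counts scale")
  groups <- as.factor(groups)
  if (length(groups) != ncol(m$values))
    stop("'groups' must have one entry per sample")
  tab <- table(groups)
  if (any(tab < 2))
    stop("each group needs at least 2 samples (",
         paste(names(tab)[tab < 2], collapse = ", "), " too small)")
  sf <- uq_scale_factors(m$values)
  lib <- colSums(m$values) * sf
  y <- sweep(m$values, 2, mean(lib) / lib, `*`)
  num <- 0; den <- 0
  for (g in levels(groups)) {
    v <- y[, groups == g, drop = FALSE]
    mu <- rowMeans(v)
    va <- apply(v, 1, stats::var)
    df <- ncol(v) - 1
    num <- num + df * ifelse(mu > 0, (va - mu) / mu^2, 0)
    den <- den + df
  }
  raw <- pmax(num / den, 0)
  center <- mean(raw, trim = trim)
  phi <- pmax((prior_df * center + den * raw) / (prior_df + den), 0)
  names(phi) <- rownames(m$values)
  phi
}

#' Negative-binomial likelihood-ratio differential expression test
#'
#' Per gene, a log-linear NB model with a two-group indicator, optional
#' unwanted-variation covariates and a log effective-library-size offset
#' (upper-quartile adjusted) is fitted, and the group coefficient is
#' tested by a likelihood-ratio test against the reduced model. The
#' reported log2 fold-change is the fitted coefficient (second group over
#' first) converted to base 2. Differential-expression calls apply three
#' gates: Bonferroni-corrected p-value below \code{p_cut}, absolute log2
#' fold-change above \code{lfc_cut}, and average log2 CPM above
#' \code{cpm_cut}.
#'
#' @param m ExpressionMatrix on the counts scale (filtered).
#' @param groups two-level factor over the samples of \code{m}; the
#'   contrast is level 2 over level 1.
#' @param w optional UnwantedVariation whose factor scores enter the
#'   design as covariates (row names must match the samples).
#' @param phi per-gene dispersions; estimated with
#'   \code{\link{estimate_dispersion}} when NULL.
#' @param p_cut Bonferroni-corrected significance gate (default 0.05).
#' @param lfc_cut absolute log2 fold-change gate, strict (default 1,
#'   i.e. >2-fold).
#' @param cpm_cut average log2 CPM gate, strict (default 3).
#' @param prior_df passed to \code{\link{estimate_dispersion}}.
#' @return data.frame of class \code{"DEResult"}: \code{gene},
#'   \code{log2fc}, \code{p_raw}, \code{p_bonf}, \code{avg_log2cpm},
#'   \code{status} (U/D/S).
#' @export
test_de <- function(m, groups, w = NULL, phi = NULL,
                    p_cut = 0.05, lfc_cut = 1, cpm_cut = 3, prior_df = 30) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "counts")
    stop("test_de requires the counts scale")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("'groups' must have exactly 2 levels")
  if (length(groups) != ncol(m$values))
    stop("'groups' must have one entry per sample")
  if (is.null(phi))
    phi <- estimate_dispersion(m, groups, prior_df = prior_df)
  if (length(phi) == 1) phi <- rep(phi, nrow(m$values))
  if (!is.null(names(phi))) phi <- phi[rownames(m$values)]
  if (length(phi) != nrow(m$values) || anyNA(phi))
    stop("'phi' must provide a dispersion for every gene")
  sf <- uq_scale_factors(m$values)
  offset <- log(colSums(m$values) * sf)
  design <- cbind(intercept = 1, group = as.numeric(groups) - 1)
  if (!is.null(w) && w$k > 0) {
    if (!identical(rownames(w$factors), colnames(m$values)))
      stop("sample mismatch between the matrix and the factor scores")
    design <- cbind(design, w$factors)
  }
  fit <- nb_glm_lrt(m$values, design, coef = 2, offset = offset, phi = phi)
  cpm <- sweep(m$values, 2, exp(offset), `/`) * 1e6
  avg <- rowMeans(log2(cpm + 1))
  G <- nrow(m$values)
  res <- data.frame(gene = rownames(m$values),
                    log2fc = fit$coef / log(2),
                    p_raw = fit$p,
                    p_bonf = pmin(1, fit$p * G),
                    avg_log2cpm = avg,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$status <- classify_status(res, p_cut = p_cut, lfc_cut = lfc_cut,
                                cpm_cut = cpm_cut)
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Apply the differential-expression gates
#'
#' A gene is called upregulated (U) or downregulated (D) when its
#' Bonferroni-corrected p-value is below \code{p_cut}, its absolute log2
#' fold-change strictly exceeds \code{lfc_cut}, and its average log2 CPM
#' strictly exceeds \code{cpm_cut}; otherwise it is stable (S). The sign
#' of the fold-change fixes U versus D.
#'
#' @param de DEResult (or any data.frame with \code{log2fc}, \code{p_bonf}
#'   and \code{avg_log2cpm} columns).
#' @param p_cut,lfc_cut,cpm_cut the three gates.
#' @return character vector of per-gene statuses in \code{de}'s row order.
#' @export
classify_status <- function(de, p_cut = 0.05, lfc_cut = 1, cpm_cut = 3) {
  sig <- de$p_bonf < p_cut & abs(de$log2fc) > lfc_cut &
    de$avg_log2cpm > cpm_cut
  ifelse(sig & de$log2fc > 0, "U", ifelse(sig, "D", "S"))
}

#' Run one condition contrast within a tissue
#'
#' Convenience wrapper: subsets \code{m} to the tissue and the two
#' conditions, optionally estimates \code{k} unwanted-variation factors
#' from control genes on the subset, and runs \code{\link{test_de}} with
#' the first condition as baseline (so \code{contrast = c("H", "A")} tests
#' NAT over healthy).
#'
#' @param m ExpressionMatrix on the counts scale (filtered).
#' @param tissue tissue label to subset to.
#' @param contrast length-2 character, baseline condition first.
#' @param controls optional control gene ids for factor estimation.
#' @param k number of unwanted factors (0 to disable).
#' @param ... passed to \code{\link{test_de}}.
#' @return DEResult.
#' @export
de_contrast <- function(m, tissue, contrast, controls = NULL, k = 0, ...) {
  stopifnot(length(contrast) == 2)
  idx <- m$samples$tissue == tissue & m$samples$condition %in% contrast
  sub <- subset_em(m, samples = idx)
  groups <- factor(sub$samples$condition, levels = contrast)
  wuv <- NULL
  if (k > 0) {
    if (is.null(controls))
      stop("control genes are required to estimate unwanted variation")
    lc <- uq_cpm(sub, log2 = TRUE)
    wuv <- estimate_unwanted(lc, controls, k = k)
  }
  test_de(sub, groups, w = wuv, ...)
}

#' Write a DE table as TSV
#'
#' @param de DEResult.
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_de_tsv <- function(de, file) {
  utils::write.table(de, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
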