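#' Filter genes by read abundance
#'
#' Retains genes with at least \code{min_count} reads in at least
#' \code{min_samples} samples. The default (10 reads in 2 samples) is the
#' inclusion rule applied throughout the pipeline before normalization,
#' differential expression and deconvolution.
#'
#' @param m ExpressionMatrix on the counts scale.
#' @param min_count minimum read count per qualifying sample.
#' @param min_samples minimum number of qualifying samples.
#' @return ExpressionMatrix restricted to the retained genes; the sample
#'   set is unchanged. Idempotent.
#' @export
filter_low_abundance <- function(m, min_count = 10, min_samples = 2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "counts")
    stop("filter_low_abundance requires the counts scale, got '", m$scale, "'")
  keep <- rowSums(m$values >= min_count) >= min_samples
  subset_em(m, genes = keep)
}

#' Upper-quartile scale factors
#'
#' Per-sample 75th percentile (linear interpolation, \code{quantile} type
#' 7) of the non-zero count fractions (count / library size), divided by
#' the across-sample mean of these percentiles so that the factors average
#' to 1. Computing the quantile on fractions rather than raw counts makes
#' upper-quartile CPM invariant to rescaling a sample's counts by a
#' positive constant; the factors capture composition differences only.
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of per-sample scale factors (mean 1).
#' @export
uq_scale_factors <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample '", colnames(counts)[lib == 0][1], "' has all-zero counts")
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    stats::quantile(x[x > 0] / lib[j], 0.75, names = FALSE)
  }, numeric(1))
  uq / mean(uq)
}

#' Upper-quartile CPM normalization
#'
#' Counts per million with upper-quartile scaling:
#' \code{CPM[g, j] = count[g, j] / (libsize[j] * scale[j]) * 1e6}, where
#' \code{scale[j]} is the sample's 75th percentile of non-zero counts
#' relative to the across-sample mean of those percentiles. With
#' \code{log2 = TRUE} returns \code{log2(CPM + pseudocount)}.
#'
#' @param m ExpressionMatrix on the counts scale (after filtering).
#' @param log2 return log2-transformed CPM.
#' @param pseudocount added before the log2 transform.
#' @return ExpressionMatrix on the \code{"cpm"} (or \code{"log2cpm"})
#'   scale. Scale factors and effective library sizes are attached as
#'   attributes \code{"uq_scale"} and \code{"effective_libsize"}.
#' @export
uq_cpm <- function(m, log2 = FALSE, pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "counts")
    stop("uq_cpm requires the counts scale, got '", m$scale, "'")
  zero <- colSums(m$values) == 0
  if (any(zero))
    stop("sample '", colnames(m$values)[zero][1], "' has all-zero counts")
  sf <- uq_scale_factors(m$values)
  lib <- colSums(m$values)
  cpm <- sweep(m$values, 2, lib * sf, `/`) * 1e6
  out <- if (log2) ExpressionMatrix(log2(cpm + pseudocount), m$samples,
                                    "log2cpm")
         else ExpressionMatrix(cpm, m$samples, "cpm")
  attr(out, "uq_scale") <- sf
  attr(out, "effective_libsize") <- lib * sf
  out
}

#' Estimate unwanted-variation factors from negative-control genes
#'
#' Factor analysis on the control genes only: each control gene's log2
#' expression is centered across samples and the first \code{k} left
#' singular vectors of the resulting sample x control-gene matrix are
#' returned as factor scores. Control genes are assumed free of condition
#' effects, so any structured variation they carry is unwanted (library
#' preparation, cohort, batch).
#'
#' @param m ExpressionMatrix on the log2cpm scale.
#' @param controls character vector of control (housekeeping) gene ids;
#'   must be a subset of the genes in \code{m}.
#' @param k number of factors (0 gives an empty factor matrix).
#' @return list of class \code{"UnwantedVariation"}: \code{factors}
#'   (sample x k orthonormal matrix), \code{k}, \code{control_genes},
#'   \code{var_explained} (fraction of control-gene variance captured).
#' @export
estimate_unwanted <- function(m, controls, k = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "log2cpm")
    stop("estimate_unwanted requires the log2cpm scale, got '", m$scale, "'")
  missing <- setdiff(controls, rownames(m$values))
  if (length(missing) == length(controls))
    stop("none of the control genes are present in the matrix")
  controls <- intersect(controls, rownames(m$values))
  n <- ncol(m$values)
  kmax <- min(length(controls), n - 1)
  if (k < 0 || k > kmax)
    stop("k must lie in [0, ", kmax,
         "] (min of #control genes and #samples - 1)")
  x <- t(m$values[controls, , drop = FALSE])   # samples x controls
  x <- scale(x, center = TRUE, scale = FALSE)
  if (k == 0) {
    w <- matrix(numeric(0), n, 0, dimnames = list(colnames(m$values), NULL))
    ve <- numeric(0)
  } else {
    sv <- svd(x, nu = k, nv = 0)
    w <- sv$u[, seq_len(k), drop = FALSE]
    dimnames(w) <- list(colnames(m$values), paste0("W", seq_len(k)))
    tot <- sum(x^2)
    ve <- if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k)
  }
  structure(list(factors = w, k = k, control_genes = controls,
                 var_explained = ve),
            class = "UnwantedVariation")
}

#' Remove estimated unwanted variation from a log-expression matrix
#'
#' Regresses each gene on the factor scores (with an intercept) and
#' subtracts the factor-explained component, leaving the gene means intact.
#' With zero factors the input is returned unchanged. Intended for
#' diagnostics and signature scoring; for count-model testing the factors
#' are passed to \code{\link{test_de}} as covariates instead.
#'
#' @param m ExpressionMatrix on the log2cpm scale.
#' @param w UnwantedVariation from \code{\link{estimate_unwanted}} on the
#'   same samples.
#' @return ExpressionMatrix of identical shape on the log2cpm scale.
#' @export
remove_unwanted <- function(m, w) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(w, "UnwantedVariation"))
  if (m$scale != "log2cpm")
    stop("remove_unwanted requires the log2cpm scale, got '", m$scale, "'")
  if (w$k == 0) return(m)
  if (!identical(rownames(w$factors), colnames(m$values)))
    stop("sample mismatch between the matrix and the factor scores")
  wf <- w$factors
  ## orthonormal W with centered columns: projection is Y %*% W %*% t(W)
  ## after removing gene means; fit explicitly to stay exact for any W
  y <- t(m$values)                               # samples x genes
  fit <- stats::lm.fit(cbind(1, wf), y)
  adj <- y - wf %*% fit$coefficients[-1, , drop = FALSE]
  ExpressionMatrix(t(adj), m$samples, "log2cpm")
}

#' Relative log expression diagnostics
#'
#' RLE is the deviation of each log2 expression value from the gene's
#' median across samples. Well-normalized data show per-sample RLE medians
#' near 0 with small spread, indistinguishable between conditions.
#'
#' @param m ExpressionMatrix on the log2cpm scale.
#' @return data.frame with one row per sample: \code{sample},
#'   \code{median} and \code{iqr} of the sample's RLE values.
#' @export
rle_stats <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "log2cpm")
    stop("rle_stats requires the log2cpm scale, got '", m$scale, "'")
  med <- apply(m$values, 1, stats::median)
  rle <- m$values - med
  data.frame(sample = colnames(m$values),
             median = apply(rle, 2, stats::median),
             iqr = apply(rle, 2, stats::IQR),
             row.names = NULL, stringsAsFactors = FALSE)
}
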