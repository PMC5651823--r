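#' Build a per-tissue reference panel of median healthy profiles
#'
#' @param m ExpressionMatrix containing at least one healthy (condition H)
#'   sample per tissue, on any abundance scale.
#' @return list of class \code{"ReferencePanel"}: \code{medians} (gene x
#'   tissue matrix of per-gene medians over the tissue's H samples),
#'   \code{tissues}, \code{scale}.
#' @export
build_reference <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  tissues <- unique(m$samples$tissue)
  med <- sapply(tissues, function(tt) {
    idx <- m$samples$tissue == tt & m$samples$condition == "H"
    if (!any(idx))
      stop("tissue '", tt, "' has no healthy (H) samples")
    apply(m$values[, idx, drop = FALSE], 1, stats::median)
  })
  med <- matrix(med, nrow = nrow(m$values),
                dimnames = list(rownames(m$values), tissues))
  structure(list(medians = med, tissues = tissues, scale = m$scale),
            class = "ReferencePanel")
}

#' Assign samples to tissues by correlation with healthy medians
#'
#' Each sample is assigned the tissue whose median healthy profile has the
#' highest Pearson correlation with the sample's expression vector
#' (computed over the shared gene universe). Ties are broken by panel
#' order and logged as warnings. Pearson correlation makes the assignment
#' invariant to positive affine transforms of a sample's profile.
#'
#' @param panel ReferencePanel from \code{\link{build_reference}}.
#' @param m ExpressionMatrix of the samples to assign.
#' @return data.frame per sample: \code{sample}, \code{tissue} (metadata
#'   label), \code{assigned}, \code{correlation}, \code{correct}. The
#'   fraction correct is attached as attribute \code{"accuracy"}.
#' @export
assign_tissue <- function(panel, m) {
  stopifnot(inherits(panel, "ReferencePanel"), inherits(m, "ExpressionMatrix"))
  shared <- intersect(rownames(panel$medians), rownames(m$values))
  if (length(shared) < 2)
    stop("fewer than 2 shared genes between panel and matrix; ",
         "correlation undefined")
  ref <- panel$medians[shared, , drop = FALSE]
  x <- m$values[shared, , drop = FALSE]
  cc <- stats::cor(x, ref)               # samples x tissues
  best <- apply(cc, 1, function(r) {
    top <- which(r == max(r))
    if (length(top) > 1)
      warning("tissue-assignment tie broken by panel order", call. = FALSE)
    top[1]
  })
  out <- data.frame(sample = colnames(m$values),
                    tissue = m$samples$tissue,
                    assigned = panel$tissues[best],
                    correlation = cc[cbind(seq_len(nrow(cc)), best)],
                    stringsAsFactors = FALSE)
  out$correct <- out$assigned == out$tissue
  attr(out, "accuracy") <- mean(out$correct)
  out
}

#' Housekeeping-gene concordance between two sample groups
#'
#' Cross-cohort comparability diagnostic: per (gene, tissue), the median
#' log2 level and the standard deviation of each housekeeping gene are
#' computed in both matrices (e.g. healthy-cohort samples vs NAT samples);
#' concordance is summarized as the Pearson correlation of the pooled
#' medians and the Spearman correlation of the pooled SDs.
#'
#' @param mH ExpressionMatrix of the first group, log2 scale expected.
#' @param mA ExpressionMatrix of the second group, same scale.
#' @param hk character vector of housekeeping gene ids.
#' @return list with \code{pearson_median}, \code{spearman_sd}, \code{n}
#'   (number of (gene, tissue) points).
#' @export
housekeeping_concordance <- function(mH, mA, hk) {
  stopifnot(inherits(mH, "ExpressionMatrix"), inherits(mA, "ExpressionMatrix"))
  genes <- Reduce(intersect, list(hk, rownames(mH$values), rownames(mA$values)))
  if (!length(genes))
    stop("housekeeping set has empty intersection with the matrices")
  tissues <- intersect(unique(mH$samples$tissue), unique(mA$samples$tissue))
  summarize <- function(m) {
    do.call(rbind, lapply(tissues, function(tt) {
      idx <- m$samples$tissue == tt
      v <- m$values[genes, idx, drop = FALSE]
      data.frame(gene = genes, tissue = tt,
                 med = apply(v, 1, stats::median),
                 sd = apply(v, 1, stats::sd),
                 stringsAsFactors = FALSE)
    }))
  }
  a <- summarize(mH)
  b <- summarize(mA)
  if (nrow(a) < 2)
    stop("need at least 2 (gene, tissue) points for a correlation")
  list(pearson_median = stats::cor(a$med, b$med),
       spearman_sd = stats::cor(a$sd, b$sd, method = "spearman"),
       n = nrow(a))
}
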