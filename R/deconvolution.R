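#' Build a two-column healthy/tumor reference signature
#'
#' Per-gene arithmetic means of the healthy and tumor samples of one
#' tissue, on the normalized (linear) abundance scale.
#'
#' @param m ExpressionMatrix (filtered, normalized abundance recommended).
#' @param tissue tissue label to build the reference for.
#' @return gene x 2 matrix with columns \code{healthy} and \code{tumor}.
#' @export
build_signature <- function(m, tissue) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  idx <- m$samples$tissue == tissue
  h <- idx & m$samples$condition == "H"
  t <- idx & m$samples$condition == "T"
  if (!any(h)) stop("tissue '", tissue, "' has no healthy (H) samples")
  if (!any(t)) stop("tissue '", tissue, "' has no tumor (T) samples")
  cbind(healthy = rowMeans(m$values[, h, drop = FALSE]),
        tumor = rowMeans(m$values[, t, drop = FALSE]))
}

#' Simplex-constrained two-reference deconvolution
#'
#' Estimates the tumor-similarity fraction f of a sample profile x as
#' \code{argmin || x - (1 - f) h - f t ||^2} subject to \code{0 <= f <= 1},
#' where h and t are the healthy and tumor reference columns. With two
#' references the quadratic program reduces to a single-variable
#' constrained least squares with the closed-form solution
#' \code{f = <x - h, t - h> / ||t - h||^2} projected onto [0, 1] -- exact
#' and deterministic, no iterative solver involved.
#'
#' @param x numeric sample profile named by gene, or a gene x sample
#'   matrix / ExpressionMatrix for multiple samples.
#' @param S gene x 2 reference from \code{\link{build_signature}}.
#' @return data.frame of class \code{"DeconvResult"}: \code{sample},
#'   \code{fraction_tumor}, \code{fraction_healthy}, \code{residual_norm}.
#' @export
deconvolve <- function(x, S) {
  if (inherits(x, "ExpressionMatrix")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                   dimnames = list(names(x), "sample1"))
  shared <- intersect(rownames(S), rownames(x))
  if (length(shared) < 2)
    stop("sample and reference share fewer than 2 genes")
  S <- S[shared, , drop = FALSE]
  x <- x[shared, , drop = FALSE]
  d <- S[, "tumor"] - S[, "healthy"]
  dn <- sum(d^2)
  if (dn == 0)
    stop("healthy and tumor reference columns are identical; ",
         "fraction unidentifiable")
  f <- pmin(1, pmax(0, colSums((x - S[, "healthy"]) * d) / dn))
  resid <- x - outer(S[, "healthy"], 1 - f) - outer(S[, "tumor"], f)
  out <- data.frame(sample = colnames(x), fraction_tumor = unname(f),
                    fraction_healthy = unname(1 - f),
                    residual_norm = unname(sqrt(colSums(resid^2))),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("DeconvResult", "data.frame")
  out
}
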