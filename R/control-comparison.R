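#' Compare tumor differential expression against healthy vs NAT controls
#'
#' Quantifies how the choice of control tissue changes tumor DE
#' conclusions: Pearson correlation of the two log2 fold-change vectors
#' (over all tested genes), DEG counts in each contrast, their overlap,
#' the two overlap fractions, and the counts of discordant genes
#' (significant in both contrasts with opposite direction).
#'
#' @param deTH DEResult for the tumor-vs-healthy contrast.
#' @param deTA DEResult for the tumor-vs-NAT contrast (same tissue).
#' @return one-row data.frame of class \code{"ControlComparison"}:
#'   \code{r_logfc}, \code{n_th}, \code{n_ta}, \code{n_both},
#'   \code{n_up_th_down_ta}, \code{n_down_th_up_ta}, \code{frac_ta_in_th},
#'   \code{frac_th_in_ta}.
#' @export
compare_controls <- function(deTH, deTA) {
  common <- intersect(deTH$gene, deTA$gene)
  if (!length(common)) stop("empty common tested-gene universe")
  a <- deTH[match(common, deTH$gene), ]
  b <- deTA[match(common, deTA$gene), ]
  sig_a <- a$status != "S"
  sig_b <- b$status != "S"
  both <- sig_a & sig_b
  out <- data.frame(
    r_logfc = stats::cor(a$log2fc, b$log2fc),
    n_th = sum(sig_a),
    n_ta = sum(sig_b),
    n_both = sum(both),
    n_up_th_down_ta = sum(both & a$status == "U" & b$status == "D"),
    n_down_th_up_ta = sum(both & a$status == "D" & b$status == "U"),
    frac_ta_in_th = if (sum(sig_b)) sum(both) / sum(sig_b) else NA_real_,
    frac_th_in_ta = if (sum(sig_a)) sum(both) / sum(sig_a) else NA_real_)
  class(out) <- c("ControlComparison", "data.frame")
  out
}
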