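#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, then member gene
#' ids. Duplicate members within a set are dropped; empty sets are
#' rejected.
#'
#' @param file path to a GMT file.
#' @return named list of character vectors; descriptions kept as attribute
#'   \code{"description"}.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  empty <- !lengths(sets)
  if (any(empty))
    stop("empty gene set(s) in ", file, ": ",
         paste(nm[empty], collapse = ", "))
  if (anyDuplicated(nm))
    stop("duplicate set names in ", file)
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param file output path.
#' @param description optional named character of per-set descriptions.
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, file, description = NULL) {
  if (is.null(description))
    description <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, file)
  invisible(file)
}

#' Single-sample gene-set enrichment (ssGSEA) score
#'
#' Per sample, genes are ranked by descending abundance (ties broken by
#' gene order, which is stable) and the score is the integrated difference
#' between the weighted in-set cumulative distribution and the uniform
#' out-of-set cumulative distribution:
#' \code{sum_i (P_in(i) - P_out(i))}, where in-set steps at position
#' \code{i} are proportional to \code{(N - i + 1)^alpha} (the descending
#' rank weight) and out-of-set steps are \code{1 / (N - n_set)}.
#'
#' @param m ExpressionMatrix on any abundance scale (the score depends on
#'   ranks only, so it is invariant to strictly monotone per-sample
#'   transforms).
#' @param set character vector of signature gene ids; must intersect the
#'   matrix and must not cover all genes.
#' @param alpha rank-weight exponent (default 0.25).
#' @param rescale if TRUE, min-max rescale the scores across samples to
#'   [0, 1] (off by default).
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(m, set, alpha = 0.25, rescale = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  genes <- rownames(m$values)
  set <- intersect(set, genes)
  if (!length(set))
    stop("gene set has no overlap with the expression matrix")
  N <- length(genes)
  if (length(set) == N)
    stop("gene set covers every gene; out-of-set distribution undefined")
  inset <- genes %in% set
  wts <- (N - seq_len(N) + 1)^alpha
  scores <- apply(m$values, 2, function(x) {
    o <- order(x, decreasing = TRUE)      # stable: ties keep gene order
    hit <- inset[o]
    pin <- cumsum(wts * hit) / sum(wts * hit)
    pout <- cumsum(!hit) / (N - sum(hit))
    sum(pin - pout)
  })
  if (rescale) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  scores
}

## Weighted GSEA running-sum enrichment score for a preranked list.
## scores must be sorted decreasing; inset is the aligned logical.
gsea_es <- function(scores, inset, p = 1) {
  nh <- sum(inset)
  hitw <- abs(scores)^p * inset
  denom <- sum(hitw)
  if (denom == 0) hitw[inset] <- 1 / nh else hitw <- hitw / denom
  run <- cumsum(hitw - (!inset) / (length(scores) - nh))
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment with permutation NES and FDR
#'
#' The enrichment score (ES) is the maximum deviation of the running sum
#' with hit increments proportional to |score|^p (p = 1) and uniform miss
#' increments. The null distribution is built by drawing \code{n_perm}
#' random gene sets of matching size (gene-tag permutation); NES divides
#' each ES by the mean absolute same-sign null ES, nominal p-values use
#' the same-sign null tail with a +1 correction, and FDR follows the
#' standard pooled positive/negative-null procedure. Sets with
#' FDR < \code{fdr_cut} are flagged significant.
#'
#' @param ranking named numeric vector (gene -> ranking metric, e.g. log2
#'   fold-change); no missing values.
#' @param sets named list of gene-id vectors; each must intersect the
#'   ranking and be smaller than it.
#' @param n_perm number of null draws per set (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param p weight exponent (default 1).
#' @param fdr_cut significance gate on FDR (default 0.01).
#' @return data.frame: \code{set}, \code{size}, \code{es}, \code{nes},
#'   \code{p_nominal}, \code{fdr}, \code{significant}.
#' @export
preranked_gsea <- function(ranking, sets, n_perm = 1000, seed = 1,
                           p = 1, fdr_cut = 0.01) {
  if (anyNA(ranking)) stop("ranking contains missing values")
  if (is.null(names(ranking))) stop("ranking must be named by gene id")
  o <- order(ranking, decreasing = TRUE)
  scores <- ranking[o]
  genes <- names(scores)
  N <- length(genes)
  sizes <- integer(length(sets))
  es <- numeric(length(sets))
  insets <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    memb <- intersect(sets[[i]], genes)
    if (!length(memb))
      stop("set '", names(sets)[i], "' does not intersect the ranking")
    if (length(memb) >= N)
      stop("set '", names(sets)[i], "' is as large as the ranking")
    insets[[i]] <- genes %in% memb
    sizes[i] <- length(memb)
    es[i] <- gsea_es(scores, insets[[i]], p)
  }
  set.seed(seed)
  null_es <- matrix(NA_real_, n_perm, length(sets))
  for (sz in unique(sizes)) {
    cols <- which(sizes == sz)
    for (b in seq_len(n_perm)) {
      inb <- logical(N)
      inb[sample.int(N, sz)] <- TRUE
      e <- gsea_es(scores, inb, p)
      null_es[b, cols] <- e
    }
  }
  nes <- numeric(length(sets)); pnom <- numeric(length(sets))
  null_nes <- null_es
  for (i in seq_along(sets)) {
    nn <- null_es[, i]
    pos <- nn[nn >= 0]; neg <- nn[nn < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    null_nes[, i] <- ifelse(nn >= 0, nn / mpos, nn / mneg)
    if (es[i] >= 0) {
      nes[i] <- es[i] / mpos
      pnom[i] <- (1 + sum(pos >= es[i])) / (1 + length(pos))
    } else {
      nes[i] <- es[i] / mneg
      pnom[i] <- (1 + sum(neg <= es[i])) / (1 + length(neg))
    }
  }
  pool <- as.vector(null_nes)
  fdr <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  data.frame(set = names(sets), size = sizes, es = es, nes = nes,
             p_nominal = pnom, fdr = fdr, significant = fdr < fdr_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise Spearman co-expression of signature genes
#'
#' @param m ExpressionMatrix.
#' @param genes gene ids to correlate (those absent from the matrix are
#'   ignored).
#' @param conditions optional condition filter (e.g. \code{"A"} for NAT
#'   samples only).
#' @return gene x gene Spearman correlation matrix with unit diagonal;
#'   constant genes give NA rows/columns and a warning.
#' @export
coexpression <- function(m, genes, conditions = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  idx <- rep(TRUE, ncol(m$values))
  if (!is.null(conditions)) idx <- m$samples$condition %in% conditions
  if (sum(idx) < 3) stop("need at least 3 samples after filtering")
  genes <- intersect(genes, rownames(m$values))
  v <- m$values[genes, idx, drop = FALSE]
  const <- apply(v, 1, function(x) length(unique(x)) == 1)
  if (any(const))
    warning("constant gene(s) reported as NA: ",
            paste(genes[const], collapse = ", "))
  cc <- suppressWarnings(stats::cor(t(v), method = "spearman"))
  cc[const, ] <- NA; cc[, const] <- NA
  diag(cc) <- ifelse(const, NA, 1)
  cc
}

#' Mann-Whitney comparison of per-sample scores between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with Bonferroni
#' correction by an external comparison count; significance is declared at
#' corrected p below \code{p_cut} (default 0.001).
#'
#' @param scores named numeric vector of per-sample scores.
#' @param groups two-level factor aligned with \code{scores}.
#' @param correction_factor number of comparisons in the family.
#' @param p_cut corrected significance threshold.
#' @return data.frame: \code{statistic} (U), \code{p_raw}, \code{p_bonf},
#'   \code{significant}.
#' @export
compare_scores <- function(scores, groups, correction_factor = 1,
                           p_cut = 0.001) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("'groups' must have exactly 2 levels")
  a <- scores[groups == levels(groups)[1]]
  b <- scores[groups == levels(groups)[2]]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  pb <- min(1, wt$p.value * correction_factor)
  data.frame(statistic = unname(wt$statistic), p_raw = wt$p.value,
             p_bonf = pb, significant = pb < p_cut)
}

#' Rank tumor-side genes by correlation with matched NAT TASA scores
#'
#' For each gene, the Spearman correlation between its expression in the
#' tumor samples and the TASA score of the matched (same-subject) NAT
#' samples is computed; genes are returned sorted by decreasing
#' correlation. Candidate upstream regulators of the NAT signature are
#' expected near the top.
#'
#' @param tasa_scores named numeric vector of TASA scores for NAT samples.
#' @param tumor_expr ExpressionMatrix of tumor samples whose metadata
#'   carries a \code{subject} column.
#' @param subjects named character vector mapping each NAT sample id to
#'   its subject id.
#' @return data.frame: \code{gene}, \code{rho}, \code{rank}, plus
#'   attribute \code{"n_pairs"}. Constant genes are excluded with a
#'   warning; unmatched samples are dropped with a warning.
#' @export
rank_regulators <- function(tasa_scores, tumor_expr, subjects) {
  stopifnot(inherits(tumor_expr, "ExpressionMatrix"))
  nat <- names(tasa_scores)
  subj_nat <- subjects[nat]
  tum <- tumor_expr$samples
  keep_t <- tum$subject %in% subj_nat
  if (!all(keep_t))
    warning(sum(!keep_t), " tumor sample(s) without a matched NAT sample; ",
            "dropped")
  tum <- tum[keep_t, , drop = FALSE]
  ord <- match(tum$subject, subj_nat)
  pair_scores <- tasa_scores[nat[ord]]
  if (anyNA(pair_scores)) {
    drop <- is.na(pair_scores)
    warning(sum(drop), " NAT sample(s) without a matched tumor; dropped")
    tum <- tum[!drop, , drop = FALSE]; pair_scores <- pair_scores[!drop]
  }
  if (length(pair_scores) < 3)
    stop("need at least 3 matched subject pairs")
  v <- tumor_expr$values[, tum$sample, drop = FALSE]
  const <- apply(v, 1, function(x) length(unique(x)) == 1)
  if (any(const))
    warning(sum(const), " constant tumor gene(s) excluded from the ranking")
  v <- v[!const, , drop = FALSE]
  rho <- suppressWarnings(
    stats::cor(t(v), pair_scores, method = "spearman")[, 1])
  out <- data.frame(gene = names(rho), rho = unname(rho),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rho), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_pairs") <- length(pair_scores)
  out
}
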