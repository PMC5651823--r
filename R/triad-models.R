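#' Combine A:H and T:A calls into the nine expression models
#'
#' Each gene's model is the concatenation of its NAT-vs-healthy status and
#' its tumor-vs-NAT status (U, D or S each), giving the nine models SS,
#' SU, SD, US, DS, UU, DD, UD, DU. UD marks tumor-adjacent specific
#' activation (TASA), DU tumor-adjacent specific repression (TASR).
#'
#' @param deAH named list of DEResult per tissue for the NAT-vs-healthy
#'   contrast.
#' @param deTA named list of DEResult per tissue for the tumor-vs-NAT
#'   contrast (same tissues, same gene universe per tissue).
#' @return data.frame of class \code{"TriadAssignment"} in long format:
#'   \code{tissue}, \code{gene}, \code{model}.
#' @export
assign_models <- function(deAH, deTA) {
  if (!setequal(names(deAH), names(deTA)))
    stop("contrast lists cover different tissues")
  out <- lapply(names(deAH), function(tt) {
    a <- deAH[[tt]]; b <- deTA[[tt]]
    if (!setequal(a$gene, b$gene)) {
      miss <- c(setdiff(a$gene, b$gene), setdiff(b$gene, a$gene))
      stop("gene universes differ between contrasts in tissue '", tt,
           "'; missing: ", paste(utils::head(miss, 10), collapse = ", "),
           if (length(miss) > 10) ", ...")
    }
    b <- b[match(a$gene, b$gene), ]
    data.frame(tissue = tt, gene = a$gene,
               model = paste0(a$status, b$status),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("TriadAssignment", "data.frame")
  out
}

#' Within-tissue enrichment of the nine expression models
#'
#' Under independence of the two contrasts, the expected number of genes
#' in model XY is \code{G * (n_X / G) * (n_Y / G)} where \code{n_X} and
#' \code{n_Y} are the marginal status counts. The upper-tail p-value is
#' Poisson with the expected count as rate.
#'
#' @param assignment TriadAssignment.
#' @param tissue tissue to summarize.
#' @return data.frame per model: \code{model}, \code{observed},
#'   \code{expected}, \code{fold}, \code{p}.
#' @export
model_enrichment <- function(assignment, tissue) {
  a <- assignment[assignment$tissue == tissue, ]
  if (!nrow(a)) stop("no assignments for tissue '", tissue, "'")
  G <- nrow(a)
  s1 <- substr(a$model, 1, 1)
  s2 <- substr(a$model, 2, 2)
  out <- do.call(rbind, lapply(NINE_MODELS, function(mod) {
    x <- substr(mod, 1, 1); y <- substr(mod, 2, 2)
    obs <- sum(a$model == mod)
    exp <- G * (sum(s1 == x) / G) * (sum(s2 == y) / G)
    if (exp == 0 && obs > 0) {
      warning("model ", mod, ": expected 0 but observed ", obs, call. = FALSE)
      data.frame(model = mod, observed = obs, expected = exp, fold = Inf,
                 p = 0)
    } else {
      data.frame(model = mod, observed = obs, expected = exp,
                 fold = if (exp > 0) obs / exp else NA_real_,
                 p = stats::ppois(obs - 1, exp, lower.tail = FALSE))
    }
  }))
  rownames(out) <- NULL
  out
}

#' Poisson-Binomial tail probability by dynamic programming
#'
#' Exact probability that at least \code{k} of \code{length(q)}
#' independent Bernoulli trials with success probabilities \code{q}
#' succeed.
#'
#' @param q per-trial success probabilities in [0, 1].
#' @param k threshold (1 <= k <= length(q)).
#' @return numeric tail probability.
#' @export
poisson_binomial_tail <- function(q, k) {
  if (any(q < 0 | q > 1)) stop("probabilities must lie in [0, 1]")
  T <- length(q)
  if (k < 1 || k > T) stop("k must lie in [1, length(q)]")
  p <- c(1, numeric(T))        # p[j+1] = P(j successes among trials so far)
  for (qi in q)
    p <- c(p[1] * (1 - qi), p[-1] * (1 - qi) + p[-(T + 1)] * qi)
  sum(p[(k + 1):(T + 1)])
}

#' Cross-tissue sharing statistics under an independence null
#'
#' The null model treats per-tissue membership (e.g. "upregulated in NAT
#' vs healthy") as independent Bernoulli events with the observed marginal
#' rates \code{q}. The chance that a given gene is a member in at least
#' \code{k} tissues is the exact Poisson-Binomial tail; the expected
#' number of such genes is \code{lambda = G * tail}, and the observed
#' count is compared with a Poisson upper tail (the Poisson approximation
#' of the Binomial over genes).
#'
#' @param q per-tissue membership probabilities.
#' @param G size of the common tested-gene universe.
#' @param k tissue-count threshold.
#' @param observed observed number of genes shared in >= k tissues.
#' @return data.frame of class \code{"SharingResult"}: \code{k},
#'   \code{observed}, \code{lambda}, \code{fold}, \code{p}.
#' @export
sharing_null <- function(q, G, k, observed) {
  if (observed > G) stop("observed count exceeds the gene universe")
  tail <- poisson_binomial_tail(q, k)
  lambda <- G * tail
  out <- data.frame(k = k, observed = observed, lambda = lambda,
                    fold = if (lambda > 0) observed / lambda else NA_real_,
                    p = stats::ppois(observed - 1, lambda,
                                     lower.tail = FALSE))
  class(out) <- c("SharingResult", "data.frame")
  out
}

#' Genes assigned a model in at least a given number of tissues
#'
#' @param assignment TriadAssignment.
#' @param model one of the nine model labels (UD extracts the shared TASA
#'   set).
#' @param min_tissues minimum number of tissues (>= 1).
#' @return character vector of gene ids, sorted.
#' @export
shared_genes <- function(assignment, model, min_tissues = 3) {
  if (min_tissues < 1) stop("min_tissues must be >= 1")
  hits <- assignment[assignment$model == model, ]
  cnt <- table(hits$gene)
  sort(names(cnt)[cnt >= min_tissues])
}

#' Cross-tissue sharing summary for one model
#'
#' Convenience wrapper computing observed shared counts and
#' \code{\link{sharing_null}} statistics for each threshold.
#'
#' @param assignment TriadAssignment.
#' @param model model label.
#' @param thresholds integer vector of minimum tissue counts.
#' @return SharingResult data.frame with one row per threshold.
#' @export
sharing_summary <- function(assignment, model, thresholds = 2:4) {
  tissues <- unique(assignment$tissue)
  common <- Reduce(intersect,
                   split(assignment$gene, assignment$tissue))
  a <- assignment[assignment$gene %in% common, ]
  G <- length(common)
  q <- vapply(tissues, function(tt)
    sum(a$tissue == tt & a$model == model) / G, numeric(1))
  out <- do.call(rbind, lapply(thresholds, function(k) {
    obs <- length(shared_genes(a, model, k))
    sharing_null(q, G, k, obs)
  }))
  class(out) <- c("SharingResult", "data.frame")
  out
}

#' Directional consistency of fold-changes across tissues
#'
#' Fraction of genes whose log2 fold-change has the same sign in every
#' tissue (statistical significance is not required). Genes missing from
#' any tissue are excluded with a warning.
#'
#' @param deAH named list of DEResult per tissue.
#' @param genes gene ids to evaluate.
#' @return fraction in [0, 1], or NA (with a warning) for an empty set.
#' @export
directional_consistency <- function(deAH, genes) {
  if (!length(genes)) {
    warning("empty gene set: directional consistency undefined")
    return(NA_real_)
  }
  present <- Reduce(intersect, lapply(deAH, function(d) d$gene))
  drop <- setdiff(genes, present)
  if (length(drop)) {
    warning(length(drop), " gene(s) not tested in every tissue; excluded")
    genes <- intersect(genes, present)
  }
  if (!length(genes)) {
    warning("no genes tested in every tissue")
    return(NA_real_)
  }
  signs <- vapply(deAH, function(d)
    sign(d$log2fc[match(genes, d$gene)]), numeric(length(genes)))
  signs <- matrix(signs, nrow = length(genes))
  mean(apply(signs, 1, function(s) all(s > 0) || all(s < 0)))
}
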