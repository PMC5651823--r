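## Vectorized negative-binomial GLM fitting (log link, known dispersion).
## All genes share one design matrix, so IRLS is run for every gene
## simultaneously: the per-gene weighted normal equations are assembled
## with matrix products and solved with closed-form inverses for p <= 3.

## Solve A beta = b for G symmetric p x p systems given as rows.
## a: G x p(p+1)/2 (upper triangle, column-major pair order), b: G x p.
solve_sym_batch <- function(a, b, p) {
  if (p == 1) return(b / a)
  if (p == 2) {
    det <- a[, 1] * a[, 3] - a[, 2]^2
    cbind((a[, 3] * b[, 1] - a[, 2] * b[, 2]) / det,
          (a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det)
  } else if (p == 3) {
    a11 <- a[, 1]; a12 <- a[, 2]; a22 <- a[, 3]
    a13 <- a[, 4]; a23 <- a[, 5]; a33 <- a[, 6]
    c11 <- a22 * a33 - a23^2
    c12 <- a13 * a23 - a12 * a33
    c13 <- a12 * a23 - a13 * a22
    c22 <- a11 * a33 - a13^2
    c23 <- a12 * a13 - a11 * a23
    c33 <- a11 * a22 - a12^2
    det <- a11 * c11 + a12 * c12 + a13 * c13
    cbind((c11 * b[, 1] + c12 * b[, 2] + c13 * b[, 3]) / det,
          (c12 * b[, 1] + c22 * b[, 2] + c23 * b[, 3]) / det,
          (c13 * b[, 1] + c23 * b[, 2] + c33 * b[, 3]) / det)
  } else {
    ## general fallback: reconstruct and solve per gene
    idx <- matrix(0L, p, p)
    kk <- 0L
    for (j in seq_len(p)) for (i in seq_len(j)) {
      kk <- kk + 1L
      idx[i, j] <- kk; idx[j, i] <- kk
    }
    t(vapply(seq_len(nrow(a)), function(g) {
      solve(matrix(a[g, idx], p, p), b[g, ])
    }, numeric(p)))
  }
}

nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  pois <- phi == 0
  out <- y
  if (any(pois)) {
    yy <- y[pois, , drop = FALSE]; mm <- mu[pois, , drop = FALSE]
    out[pois, ] <- 2 * (t1[pois, , drop = FALSE] - (yy - mm))
  }
  if (any(!pois)) {
    ph <- phi[!pois]
    yy <- y[!pois, , drop = FALSE]; mm <- mu[!pois, , drop = FALSE]
    out[!pois, ] <- 2 * (t1[!pois, , drop = FALSE] -
      (yy + 1 / ph) * log((1 + ph * yy) / (1 + ph * mm)))
  }
  rowSums(out)
}

## Fit log-linear NB models for all genes at once.
## y: G x n counts; design: n x p (full column rank); offset: length n;
## phi: length G dispersions. Returns coefficients (G x p, natural-log
## scale), fitted means and per-gene deviance.
nb_glm_fit <- function(y, design, offset, phi, maxit = 50, tol = 1e-10) {
  G <- nrow(y); n <- ncol(y); p <- ncol(design)
  if (qr(design)$rank < p)
    stop("singular design matrix: a covariate is collinear with the group ",
         "indicator; consider reducing the number of unwanted-variation ",
         "factors (k)")
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  xx <- design[, pairs[, 1], drop = FALSE] * design[, pairs[, 2], drop = FALSE]
  off <- matrix(offset, G, n, byrow = TRUE)
  mu <- pmax(y, 1 / 6) + 1e-8
  eta <- log(mu)
  dev <- nb_deviance(y, mu, phi)
  beta <- NULL
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - off) + (y - mu) / mu
    a <- w %*% xx                      # G x p(p+1)/2
    b <- (w * z) %*% design            # G x p
    beta_new <- solve_sym_batch(a, b, p)
    eta_new <- pmin(pmax(beta_new %*% t(design) + off, -30), 700)
    mu_new <- exp(eta_new)
    dev_new <- nb_deviance(y, mu_new, phi)
    ## step-halve genes whose deviance got worse
    worse <- which(dev_new > dev + 1e-8)
    half <- 0
    while (length(worse) && !is.null(beta) && half < 10) {
      beta_new[worse, ] <- (beta_new[worse, , drop = FALSE] +
                            beta[worse, , drop = FALSE]) / 2
      eta_new[worse, ] <- pmin(pmax(beta_new[worse, , drop = FALSE] %*%
                               t(design) + off[worse, , drop = FALSE], -30), 700)
      mu_new[worse, ] <- exp(eta_new[worse, , drop = FALSE])
      dev_new[worse] <- nb_deviance(y[worse, , drop = FALSE],
                                    mu_new[worse, , drop = FALSE],
                                    phi[worse])
      worse <- worse[dev_new[worse] > dev[worse] + 1e-8]
      half <- half + 1
    }
    delta <- max(abs(dev_new - dev))
    beta <- beta_new; eta <- eta_new; mu <- mu_new; dev <- dev_new
    if (delta < tol * (mean(abs(dev)) + 1)) break
  }
  list(coefficients = beta, fitted = mu, deviance = dev)
}

## Likelihood-ratio test of one design column across all genes.
## Returns natural-log coefficient, LRT statistic and p-value per gene.
nb_glm_lrt <- function(y, design, coef, offset, phi) {
  full <- nb_glm_fit(y, design, offset, phi)
  red <- nb_glm_fit(y, design[, -coef, drop = FALSE], offset, phi)
  lr <- pmax(red$deviance - full$deviance, 0)
  list(coef = full$coefficients[, coef],
       lr = lr,
       p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}
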