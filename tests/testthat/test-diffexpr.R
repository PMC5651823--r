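test_that("dispersion estimates track the truth for Poisson and NB counts", {
  set.seed(10)
  n <- 50; G <- 800
  grp <- factor(rep(c("a", "b"), each = n))
  pois <- toy_em(matrix(rpois(G * 2 * n, 100), G))
  phi_p <- estimate_dispersion(pois, grp)
  expect_lte(median(phi_p), 0.05)
  expect_true(all(phi_p >= 0))

  nb <- toy_em(matrix(rnbinom(G * 2 * n, mu = 100, size = 1 / 0.4), G))
  phi_nb <- estimate_dispersion(nb, grp)
  expect_gt(mean(phi_nb), 0.3)
  expect_lt(mean(phi_nb), 0.5)

  const <- toy_em(matrix(7, 20, 8))
  expect_equal(unname(estimate_dispersion(const, rep(c("a", "b"), 4))),
               rep(0, 20))

  expect_error(estimate_dispersion(nb, rep(c("a", "b", "b"), length.out = 2 * n)),
               NA)
  expect_error(estimate_dispersion(nb, c("a", rep("b", 2 * n - 1))),
               "at least 2 samples")
})

test_that("genes with identical counts in both groups are stable with zero fold-change", {
  set.seed(11)
  base <- matrix(rnbinom(100 * 10, mu = 200, size = 5), 100)
  m <- toy_em(cbind(base, base))
  grp <- factor(rep(c("g1", "g2"), each = 10))
  de <- test_de(m, grp, phi = rep(0.2, 100))
  expect_equal(de$log2fc, rep(0, 100), tolerance = 1e-6)
  expect_true(all(de$status == "S"))
})

test_that("swapping group labels negates fold-changes and preserves p-values", {
  set.seed(12)
  m <- toy_em(matrix(rnbinom(150 * 20, mu = 150, size = 5), 150))
  grp <- factor(rep(c("g1", "g2"), each = 10))
  phi <- estimate_dispersion(m, grp)
  d1 <- test_de(m, grp, phi = phi)
  d2 <- test_de(m, factor(grp, levels = c("g2", "g1")), phi = phi)
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-8)
  expect_equal(d1$p_raw, d2$p_raw, tolerance = 1e-10)
})

test_that("with zero dispersion the LRT matches a Poisson GLM oracle", {
  set.seed(13)
  G <- 15; n <- 12
  m <- toy_em(matrix(rpois(G * n, 80), G))
  m$values[1:5, 7:12] <- m$values[1:5, 7:12] * 3
  grp <- factor(rep(c("g1", "g2"), each = 6))
  de <- test_de(m, grp, phi = rep(0, G))
  off <- log(colSums(m$values) * uq_scale_factors(m$values))
  oracle <- t(sapply(seq_len(G), function(g) {
    y <- m$values[g, ]
    full <- glm(y ~ grp + offset(off), family = poisson())
    red <- glm(y ~ 1 + offset(off), family = poisson())
    c(coef(full)[2] / log(2), anova(red, full, test = "LRT")$`Pr(>Chi)`[2])
  }))
  expect_equal(de$log2fc, oracle[, 1], tolerance = 1e-6)
  expect_equal(de$p_raw, oracle[, 2], tolerance = 1e-6)
})

test_that("the NB fit agrees with edgeR's GLM on shared offsets and dispersions", {
  set.seed(14)
  G <- 40; n <- 16
  y <- matrix(rnbinom(G * n, mu = 120, size = 1 / 0.15), G)
  y[1:6, 9:16] <- y[1:6, 9:16] * 4
  m <- toy_em(y)
  grp <- factor(rep(c("g1", "g2"), each = 8))
  phi <- rep(0.15, G)
  de <- test_de(m, grp, phi = phi)

  off <- log(colSums(y) * uq_scale_factors(y))
  design <- model.matrix(~grp)
  fit <- edgeR::glmFit(y, design, dispersion = phi, offset = off,
                       prior.count = 0)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  expect_equal(de$log2fc, unname(lrt$table$logFC), tolerance = 1e-4)
  expect_equal(de$p_raw, unname(lrt$table$PValue), tolerance = 1e-4)
})

test_that("the three DE gates are applied deterministically", {
  de <- data.frame(log2fc = c(1.5, 0.8, 3, -1.5, 1.5),
                   p_bonf = c(0.01, 0.01, 0.2, 0.01, 0.01),
                   avg_log2cpm = c(4, 4, 6, 4, 2))
  expect_identical(classify_status(de), c("U", "S", "S", "D", "S"))
})

test_that("Bonferroni correction is monotone in the number of tested genes", {
  set.seed(15)
  m <- toy_em(matrix(rnbinom(200 * 12, mu = 90, size = 8), 200))
  grp <- factor(rep(c("g1", "g2"), each = 6))
  full <- test_de(m, grp, phi = rep(0.1, 200))
  sub <- test_de(subset_em(m, genes = 1:50), grp, phi = rep(0.1, 50))
  shared <- intersect(full$gene, sub$gene)
  expect_true(all(full$p_bonf[match(shared, full$gene)] >=
                  sub$p_bonf[match(shared, sub$gene)] - 1e-12))
})

test_that("a covariate collinear with the group indicator is rejected", {
  set.seed(16)
  m <- toy_em(matrix(rnbinom(50 * 10, mu = 100, size = 5), 50))
  grp <- factor(rep(c("g1", "g2"), each = 5))
  w <- structure(list(factors = matrix(as.numeric(grp) - 1, 10, 1,
                                       dimnames = list(colnames(m$values),
                                                       "W1")),
                      k = 1L, control_genes = character(0)),
                 class = "UnwantedVariation")
  expect_error(test_de(m, grp, w = w, phi = rep(0.1, 50)),
               "collinear|singular")
})
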