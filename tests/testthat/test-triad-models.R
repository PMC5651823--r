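fake_de <- function(genes, status, lfc = NULL) {
  if (is.null(lfc))
    lfc <- ifelse(status == "U", 2, ifelse(status == "D", -2, 0))
  structure(data.frame(gene = genes, log2fc = lfc, p_raw = 0.5,
                       p_bonf = 1, avg_log2cpm = 5, status = status,
                       stringsAsFactors = FALSE),
            class = c("DEResult", "data.frame"))
}

test_that("model assignment concatenates the two contrast statuses", {
  g <- c("g1", "g2", "g3")
  ah <- list(t1 = fake_de(g, c("U", "S", "D")))
  ta <- list(t1 = fake_de(g, c("D", "S", "D")))
  mod <- assign_models(ah, ta)
  expect_identical(mod$model, c("UD", "SS", "DD"))
  expect_equal(nrow(mod), 3)

  ta_bad <- list(t1 = fake_de(c("g1", "g2", "gX"), c("D", "S", "D")))
  expect_error(assign_models(ah, ta_bad), "gene universes differ.*gX")
})

test_that("model enrichment reproduces the observed/expected arithmetic", {
  G <- 1000
  s1 <- c(rep("U", 100), rep("S", 900))
  s2 <- c(rep("D", 38), rep("S", 62), rep("D", 62), rep("S", 838))
  mod <- data.frame(tissue = "t1", gene = sprintf("g%04d", 1:G),
                    model = paste0(s1, s2))
  class(mod) <- c("TriadAssignment", "data.frame")
  enr <- model_enrichment(mod, "t1")
  ud <- enr[enr$model == "UD", ]
  expect_equal(ud$observed, 38)
  expect_equal(ud$expected, 10)   # 1000 * (100/1000) * (100/1000)
  expect_equal(ud$fold, 3.8)
  expect_equal(ud$p, ppois(37, 10, lower.tail = FALSE))
  expect_equal(sum(enr$observed), G)

  ## observed 0 with positive expectation: fold 0, upper-tail p = 1
  mod2 <- mod
  mod2$model[s1 == "U" & s2 == "D"] <- "US"
  enr2 <- model_enrichment(mod2, "t1")
  expect_equal(enr2$fold[enr2$model == "UD"], 0)
  expect_equal(enr2$p[enr2$model == "UD"], 1)
})

test_that("model enrichment is calibrated under independent statuses", {
  set.seed(20)
  folds <- replicate(100, {
    G <- 2000
    s1 <- sample(c("U", "D", "S"), G, replace = TRUE, prob = c(.1, .1, .8))
    s2 <- sample(c("U", "D", "S"), G, replace = TRUE, prob = c(.15, .15, .7))
    mod <- data.frame(tissue = "t1", gene = seq_len(G),
                      model = paste0(s1, s2))
    class(mod) <- c("TriadAssignment", "data.frame")
    mean(model_enrichment(mod, "t1")$fold)
  })
  expect_gt(mean(folds), 0.9)
  expect_lt(mean(folds), 1.1)
})

test_that("Poisson-Binomial tail equals exhaustive enumeration and Binomial closed forms", {
  set.seed(21)
  enum_tail <- function(q, k) {
    T <- length(q)
    states <- expand.grid(rep(list(0:1), T))
    pr <- apply(states, 1, function(s) prod(ifelse(s == 1, q, 1 - q)))
    sum(pr[rowSums(states) >= k])
  }
  for (T in 2:6) {
    q <- runif(T)
    for (k in 1:T)
      expect_equal(poisson_binomial_tail(q, k), enum_tail(q, k),
                   tolerance = 1e-12)
  }
  ## equal probabilities reduce to the Binomial tail
  for (k in 1:5)
    expect_equal(poisson_binomial_tail(rep(0.3, 5), k),
                 pbinom(k - 1, 5, 0.3, lower.tail = FALSE),
                 tolerance = 1e-12)
  ## hand case: 3 fair coins, at least 2 heads
  expect_equal(poisson_binomial_tail(rep(0.5, 3), 2), 0.5, tolerance = 1e-12)
})

test_that("sharing statistics follow the Poisson approximation", {
  s <- sharing_null(q = 0.1, G = 100, k = 1, observed = 10)
  expect_equal(s$lambda, 10)
  expect_equal(s$fold, 1)

  ## closed-form Poisson tail at lambda = 0.01, observed = 2
  s2 <- sharing_null(q = c(0.01, 0.01), G = 100, k = 2, observed = 2)
  expect_equal(s2$lambda, 0.01, tolerance = 1e-12)
  expect_equal(s2$p, 1 - exp(-0.01) * (1 + 0.01), tolerance = 1e-10)

  expect_error(sharing_null(0.1, G = 10, k = 1, observed = 11),
               "exceeds")
})

test_that("shared gene extraction respects the tissue threshold", {
  mod <- data.frame(
    tissue = rep(c("t1", "t2", "t3", "t4"), each = 3),
    gene = rep(c("a", "b", "c"), 4),
    model = c("UD", "UD", "SS",  "UD", "UD", "SS",
              "UD", "SS", "SS",  "SS", "SS", "UD"))
  class(mod) <- c("TriadAssignment", "data.frame")
  expect_identical(shared_genes(mod, "UD", 3), "a")
  expect_identical(shared_genes(mod, "UD", 2), c("a", "b"))
  expect_setequal(shared_genes(mod, "UD", 1), c("a", "b", "c"))
  expect_error(shared_genes(mod, "UD", 0), ">= 1")
})

test_that("directional consistency matches enumeration expectations", {
  g <- sprintf("g%04d", 1:4000)
  allpos <- lapply(1:4, function(i) fake_de(g, rep("S", 4000),
                                            lfc = runif(4000, 0.1, 2)))
  expect_equal(directional_consistency(allpos, g), 1)

  set.seed(22)
  rnd <- lapply(1:4, function(i) fake_de(g, rep("S", 4000),
                                         lfc = sample(c(-1, 1), 4000, TRUE)))
  frac <- directional_consistency(rnd, g)
  ## expected 2 * (1/2)^4 = 0.125; binomial sd ~ 0.0052
  expect_lt(abs(frac - 0.125), 0.02)

  expect_warning(out <- directional_consistency(allpos, character(0)),
                 "empty")
  expect_true(is.na(out))
  expect_warning(directional_consistency(allpos, c(g[1], "missing")),
                 "excluded")
})
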