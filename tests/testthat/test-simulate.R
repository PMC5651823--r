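test_that("identical seeds give bitwise-identical simulations", {
  cf <- small_triad_config(seed = 42)
  a <- simulate_triad(cf)
  b <- simulate_triad(cf)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$deg_membership, b$truth$deg_membership)
  expect_identical(a$truth$mixing_fraction, b$truth$mixing_fraction)
})

test_that("counts are non-negative integers and metadata is complete", {
  sim <- simulate_triad(small_triad_config())
  v <- sim$matrix$values
  expect_true(all(v >= 0))
  expect_identical(v, round(v))
  expect_setequal(unique(sim$matrix$samples$condition), c("H", "A", "T"))
  expect_identical(names(sim$truth$mixing_fraction),
                   sim$matrix$samples$sample[sim$matrix$samples$condition == "A"])
})

test_that("shared TASA construction guarantee holds", {
  cf <- simulation_config(n_genes = 500, n_tissues = 4, n_shared_tasa = 20,
                          min_shared_tissues = 3,
                          samples_per_condition = c(H = 4, A = 4, T = 4),
                          n_housekeeping = 30, seed = 3)
  tr <- simulate_triad(cf)$truth
  expect_length(tr$tasa_shared, 20)
  ud_counts <- with(subset(tr$deg_membership, model == "UD"), table(gene))
  expect_true(all(ud_counts[tr$tasa_shared] >= 3))
})

test_that("model proportions summing above 1 are rejected with the map named", {
  expect_error(
    simulation_config(model_proportions = c(UD = 0.6, DU = 0.6)),
    "model_proportions sum to.*UD")
  expect_error(simulation_config(model_proportions = c(XX = 0.1)),
               "unknown expression models")
})

test_that("null-gene counts match negative-binomial moments", {
  cf <- simulation_config(
    n_genes = 60, n_tissues = 1,
    samples_per_condition = c(H = 1200, A = 2, T = 2),
    dispersion = 0.3,
    libsize_by_source = list(src = c(meanlog = log(1e7), sdlog = 0)),
    n_unwanted_factors = 0, n_housekeeping = 5,
    model_proportions = c(UD = 0), n_shared_tasa = 0,
    min_shared_tissues = 1, seed = 11)
  sim <- simulate_triad(cf)
  h <- sim$matrix$values[, sim$matrix$samples$condition == "H"]
  mu <- rowMeans(h)
  v <- apply(h, 1, var)
  expected <- mu + 0.3 * mu^2
  ## Monte-Carlo tolerance at n = 1200: variance of a variance is large,
  ## so compare in aggregate and per gene within a generous band
  expect_lt(abs(median(v / expected) - 1), 0.15)
  expect_gt(cor(log(v), log(expected)), 0.99)
})

test_that("housekeeping genes carry no condition effect", {
  frac_clean <- sapply(1:3, function(sd) {
    sim <- simulate_triad(small_triad_config(seed = sd,
                                             n_unwanted_factors = 0))
    lc <- uq_cpm(filter_low_abundance(sim$matrix), log2 = TRUE)
    hk <- intersect(sim$truth$housekeeping, rownames(lc$values))
    idx <- lc$samples$tissue == "tissue01"
    grp <- lc$samples$condition[idx]
    p <- apply(lc$values[hk, idx], 1, function(x)
      t.test(x[grp == "H"], x[grp == "A"])$p.value)
    mean(p > 0.01)
  })
  expect_gte(mean(frac_clean), 0.98)
})

test_that("library-size ratio between sources matches the configuration", {
  cf <- simulation_config(
    n_genes = 400, n_tissues = 1,
    samples_per_condition = c(H = 60, A = 30, T = 30),
    libsize_by_source = list(a = c(meanlog = log(5e6), sdlog = 0.1),
                             b = c(meanlog = log(2e7), sdlog = 0.1)),
    n_unwanted_factors = 0, n_housekeeping = 20,
    model_proportions = c(UD = 0), n_shared_tasa = 0,
    min_shared_tissues = 1, seed = 5)
  sim <- simulate_triad(cf)
  lib <- colSums(sim$matrix$values)
  src <- sim$matrix$samples$source
  ratio <- mean(lib[src == "b"]) / mean(lib[src == "a"])
  expect_lt(abs(ratio / 4 - 1), 0.1)
})

test_that("matched-pairs simulation emits matching subject ids", {
  cf <- simulation_config(
    n_genes = 300, n_tissues = 1,
    samples_per_condition = c(H = 5, A = 10, T = 10),
    n_housekeeping = 20, n_shared_tasa = 6, min_shared_tissues = 1,
    driver_effect = 0, seed = 2)
  sim <- simulate_matched_pairs(cf)
  s <- sim$matrix$samples
  expect_equal(sum(s$condition == "A"), 10)
  expect_equal(sum(s$condition == "T"), 10)
  expect_setequal(s$subject[s$condition == "A"],
                  s$subject[s$condition == "T"])
  expect_false(is.na(sim$truth$driver_gene))
})

test_that("with no driver effect the tumor driver level is uninformative", {
  rho <- sapply(1:4, function(sd) {
    cf <- simulation_config(
      n_genes = 400, n_tissues = 1,
      samples_per_condition = c(H = 5, A = 120, T = 120),
      n_housekeeping = 20, n_shared_tasa = 10, min_shared_tissues = 1,
      driver_effect = 0, seed = sd)
    sim <- simulate_matched_pairs(cf)
    cpm <- uq_cpm(filter_low_abundance(sim$matrix))
    nat <- subset_em(cpm, samples = cpm$samples$condition == "A")
    tum <- subset_em(cpm, samples = cpm$samples$condition == "T")
    sc <- ssgsea_score(nat, sim$truth$tasa_shared)
    subj <- match(tum$samples$subject, nat$samples$subject)
    cor(tum$values[sim$truth$driver_gene, ], sc[subj], method = "spearman")
  })
  expect_lt(abs(mean(rho)), 0.15)
})
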