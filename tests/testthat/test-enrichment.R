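test_that("GMT files round-trip and empty sets are rejected", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f, description = c(alpha = "first", beta = "second"))
  back <- read_gmt(f)
  expect_equal(back, sets, ignore_attr = TRUE)
  expect_identical(attr(back, "description")[["alpha"]], "first")

  writeLines("empty\tna", f)
  expect_error(read_gmt(f), "empty gene set")

  bundled <- read_gmt(system.file("extdata", "toy_hallmarks.gmt",
                                  package = "nattriad"))
  expect_length(bundled, 3)
  expect_true(all(lengths(bundled) >= 7))
})

test_that("ssGSEA reproduces the hand-computed toy score", {
  ## 4 genes, the set is the single top-ranked gene, alpha = 0:
  ## P_in = (1,1,1,1); P_out = (0, 1/3, 2/3, 1); sum of differences = 2
  m <- toy_em(cbind(s1 = c(40, 30, 20, 10)), scale = "abundance")
  expect_equal(unname(ssgsea_score(m, "g001", alpha = 0)), 2, tolerance = 1e-10)

  ## bottom-ranked gene is maximally depleted
  expect_equal(unname(ssgsea_score(m, "g004", alpha = 0)), -2, tolerance = 1e-10)

  expect_error(ssgsea_score(m, rownames(m$values)), "every gene")
  expect_error(ssgsea_score(m, "nope"), "no overlap")
})

test_that("ssGSEA is rank-based and monotone in set-gene abundance", {
  set.seed(30)
  vals <- matrix(rlnorm(200 * 10, 3, 1), 200)
  m <- toy_em(vals, scale = "abundance")
  set <- rownames(m$values)[sample(200, 15)]
  s1 <- ssgsea_score(m, set)
  mono <- m
  mono$values <- log2(m$values + 1)          # strictly monotone transform
  expect_equal(ssgsea_score(mono, set), s1, tolerance = 1e-12)

  up <- m
  up$values[set, 3] <- up$values[set, 3] * 4  # shift set genes up in s3
  s2 <- ssgsea_score(up, set)
  expect_gte(s2[3], s1[3])
  expect_equal(s2[-3], s1[-3], tolerance = 1e-12)
})

test_that("preranked ES matches hand values and is antisymmetric", {
  rk <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  out <- preranked_gsea(rk, list(top = "a"), n_perm = 50, seed = 1)
  expect_equal(out$es, 1, tolerance = 1e-10)    # running sum peaks at once

  sets <- list(s1 = c("a", "c"), s2 = c("d", "e"))
  pos <- preranked_gsea(rk, sets, n_perm = 100, seed = 2)
  neg <- preranked_gsea(-rk, sets, n_perm = 100, seed = 2)
  expect_equal(pos$es, -neg$es, tolerance = 1e-12)

  expect_true(all(abs(pos$es) <= 1))
  expect_true(all(pos$p_nominal >= 1 / 101))
  expect_error(preranked_gsea(rk, list(all = names(rk))), "as large as")
  expect_error(preranked_gsea(c(rk, f = NA), list(s = "a")), "missing")
})

test_that("preranked ES agrees with fgsea on a moderate example", {
  set.seed(31)
  rk <- sort(rnorm(300), decreasing = TRUE)
  names(rk) <- sprintf("g%03d", 1:300)
  sets <- list(s1 = names(rk)[c(3, 17, 40, 200)],
               s2 = names(rk)[c(250, 270, 290, 299)],
               s3 = sample(names(rk), 25))
  mine <- preranked_gsea(rk, sets, n_perm = 100, seed = 3)
  ref <- suppressWarnings(
    fgsea::fgsea(sets, rk, scoreType = "std", nPermSimple = 500))
  expect_equal(mine$es, ref$ES[match(mine$set, ref$pathway)],
               tolerance = 1e-10)
})

test_that("co-expression is rank-invariant and flags constant genes", {
  set.seed(32)
  vals <- matrix(rlnorm(30 * 40), 30)
  m <- toy_em(vals, condition = rep("A", 40), scale = "abundance")
  genes <- rownames(m$values)[1:6]

  dup <- m
  dup$values[2, ] <- dup$values[1, ]          # duplicated profile
  cc <- coexpression(dup, genes, conditions = "A")
  expect_equal(cc[1, 2], 1)
  expect_equal(diag(cc), rep(1, 6), ignore_attr = TRUE)

  mono <- m
  mono$values[3, ] <- exp(m$values[3, ])      # monotone transform
  expect_equal(coexpression(mono, genes)[3, ],
               coexpression(m, genes)[3, ], tolerance = 1e-12)

  const <- m
  const$values[4, ] <- 2
  expect_warning(cc2 <- coexpression(const, genes), "constant")
  expect_true(all(is.na(cc2[4, ])))

  expect_error(coexpression(subset_em(m, samples = 1:2), genes),
               "at least 3")
})

test_that("score comparisons use the exact Mann-Whitney distribution", {
  ## identical multisets: p ~ 1
  s <- c(1:10, 1:10)
  g <- rep(c("a", "b"), each = 10)
  expect_gt(compare_scores(s, g)$p_raw, 0.9)

  ## complete separation, n = 10 vs 10: two-sided exact p = 2 / C(20, 10)
  s2 <- c(1:10, 101:110)
  out <- compare_scores(s2, g, correction_factor = 3)
  expect_equal(out$p_raw, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(out$p_bonf, 3 * 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(out$significant)

  ## a singleton group still yields a valid test
  expect_gt(compare_scores(c(5, 1:9), c("a", rep("b", 9)))$p_raw, 0.05)
  expect_error(compare_scores(1:5, rep("a", 5)), "2 levels")
})

test_that("regulator ranking drops unusable genes and demands 3 pairs", {
  set.seed(33)
  n <- 20
  vals <- matrix(rlnorm(50 * n), 50)
  colnames(vals) <- sprintf("T%02d", 1:n)
  tum <- toy_em(vals, condition = rep("T", n), scale = "abundance")
  tum$samples$subject <- sprintf("subj%02d", 1:n)
  tum$values[7, ] <- 3                       # constant gene
  scores <- setNames(rnorm(n), sprintf("A%02d", 1:n))
  subjects <- setNames(sprintf("subj%02d", 1:n), names(scores))

  expect_warning(rk <- rank_regulators(scores, tum, subjects), "constant")
  expect_false("g007" %in% rk$gene)
  expect_equal(nrow(rk), 49)
  expect_identical(rk$rho, sort(rk$rho, decreasing = TRUE))

  expect_error(rank_regulators(scores[1:2], tum, subjects), "3 matched")
})
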