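# Overlap coefficient, hypergeometric enrichment, gene-set scoring, state
# assignment, signature recipes, cosine co-expression.

test_that("overlap_coefficient: examples and properties", {
  expect_equal(overlap_coefficient(c("a"), c("a")), 1)
  expect_equal(overlap_coefficient(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_coefficient(c("a", "b", "c"), c("b", "c", "d", "e")), 2 / 3)
  expect_error(overlap_coefficient(character(), "a"), "non-empty")
  set.seed(16)
  for (i in 1:20) {
    a <- sample(letters, sample(3:10, 1))
    b <- sample(letters, sample(3:10, 1))
    expect_equal(overlap_coefficient(a, b), overlap_coefficient(b, a))
    expect_true(overlap_coefficient(a, b) >= 0 && overlap_coefficient(a, b) <= 1)
    expect_equal(overlap_coefficient(a, c(a, b)), 1)  # A subset of B
  }
})

test_that("hypergeom_enrich matches exhaustive enumeration", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(path = universe[1:5])
  markers <- c(universe[1:3], universe[10:11])  # n = 5, k = 3
  res <- hypergeom_enrich(markers, sets, universe)
  expect_equal(res$k, 3); expect_equal(res$K, 5); expect_equal(res$n, 5)
  expect_equal(res$p, hyper_tail_enum(3, 5, 20, 5), tolerance = 1e-12)
  expect_equal(res$p, 0.07262, tolerance = 1e-4)

  # k = 0 -> p = 1; k = n = K -> p = 1 / C(N, n)
  res0 <- hypergeom_enrich(universe[10:14], list(path = universe[1:5]), universe)
  expect_equal(res0$p, 1)
  resx <- hypergeom_enrich(universe[1:5], list(path = universe[1:5]), universe)
  expect_equal(resx$p, 1 / choose(20, 5), tolerance = 1e-12)
})

test_that("hypergeometric p equals the printed cumulative formula (N <= 60)", {
  set.seed(17)
  for (i in 1:25) {
    N <- sample(20:60, 1); K <- sample(3:15, 1); n <- sample(3:15, 1)
    k <- sample(0:min(n, K), 1)
    direct <- sum(sapply(k:n, function(i2)
      if (i2 <= K && n - i2 <= N - K)
        choose(K, i2) * choose(N - K, n - i2) / choose(N, n) else 0))
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE), direct,
                 tolerance = 1e-12)
  }
})

test_that("hypergeom_enrich filters sizes and applies the dual significance rule", {
  universe <- sprintf("u%03d", 1:200)
  sets <- list(tiny = universe[1:2],                # size 2 -> filtered
               good = universe[1:10],
               weak = universe[101:110])
  res <- hypergeom_enrich(universe[1:10], sets, universe)
  expect_setequal(res$set, c("good", "weak"))
  good <- res[res$set == "good", ]
  expect_true(good$significant)                    # k = 10, tiny p
  expect_false(res[res$set == "weak", "significant"])  # k = 0
  # overlap below 3 is never significant regardless of p
  res2 <- hypergeom_enrich(universe[1:2], list(s = universe[1:3]), universe,
                           min_overlap = 3)
  expect_false(res2$significant)
})

test_that("rank-KS gene-set score: direction, null centring, monotonicity", {
  set.seed(18)
  G <- 200
  expr <- matrix(rnorm(G * 50), G, 50,
                 dimnames = list(sprintf("g%03d", 1:G), sprintf("c%02d", 1:50)))
  set <- rownames(expr)[1:10]
  up <- expr; up[set, ] <- up[set, ] + 10
  s_up <- score_gene_set(up, set)
  expect_true(all(s_up > 0.9))

  # random set under exchangeable noise: median score near zero
  big <- matrix(rnorm(G * 2000), G, 2000,
                dimnames = list(rownames(expr), sprintf("c%04d", 1:2000)))
  s_null <- score_gene_set(big, sample(rownames(expr), 20))
  expect_lt(abs(median(s_null)), 0.05)
  expect_true(all(abs(s_null) <= 1))

  # raising set-gene expression never lowers the score
  for (i in 1:10) {
    base <- matrix(rnorm(G), G, 1, dimnames = list(rownames(expr), "c"))
    raised <- base; raised[set, ] <- raised[set, ] + runif(1, 0.1, 3)
    expect_gte(score_gene_set(raised, set), score_gene_set(base, set))
  }
  expect_error(score_gene_set(expr, "g001"), "fewer than 2")
})

test_that("assign_states follows the positive-argmax rule", {
  sc <- rbind(c(-0.2, -0.1), c(0.3, 0.1), c(0.1, 0.3), c(0.2, 0.2))
  colnames(sc) <- c("MC0", "MC1")
  expect_identical(assign_states(sc), c("unassigned", "MC0", "MC1", "MC0"))
  # permutation equivariance apart from the documented tie-break
  sc2 <- sc[, c(2, 1)]
  got <- assign_states(sc2)
  expect_identical(got[1:3], c("unassigned", "MC0", "MC1"))
  expect_identical(got[4], "MC1")  # tie now resolves to the first column
})

test_that("positive_fraction computes per-subject fractions and tests", {
  scores <- c(1, 1, -1, 1, -1, -1, 1, -1)
  groups <- rep(c("pre", "post"), each = 4)
  subj <- rep(c("p1", "p2"), times = 4)
  pf <- positive_fraction(scores, groups, subj, paired = TRUE)
  expect_equal(dim(pf$fractions), c(2, 2))
  expect_true(pf$p >= 0 && pf$p <= 1)
  # identical groups: p = 1 by convention (zero-variance differences)
  same <- positive_fraction(rep(c(1, -1), 8), rep(c("a", "b"), each = 8),
                            rep(sprintf("s%d", 1:4), times = 4), paired = TRUE)
  expect_equal(same$p, 1)
})

test_that("paired positive-fraction test has power at planted enrichment", {
  set.seed(19)
  hits <- replicate(200, {
    pre <- rbinom(10, 50, 0.6) / 50
    post <- rbinom(10, 50, 0.3) / 50
    sdd <- sd(pre - post)
    if (sdd == 0) TRUE else t.test(pre, post, paired = TRUE)$p.value < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("pseudo-bulk signature recipes", {
  pb <- rbind(a = c(2, 4, 6), b = c(4, 2, 6), c = c(1, 1, 1), d = c(3, 5, 1))
  colnames(pb) <- paste0("mc", 1:3)
  # mean recipe on a 2-gene set: pseudo-bulk (2, 4) -> 3
  expect_equal(unname(pseudobulk_signature(pb, c("a", "b"), "mean")[1]), 3)
  # scaled-negsum equals minus the column sums of row-z-scored values
  z <- t(scale(t(pb[c("a", "b", "d"), ])))
  expect_equal(pseudobulk_signature(pb, c("a", "b", "d"), "scaled-negsum"),
               -colSums(z))
  # constant gene contributes zero after scaling; all-constant set -> scores 0
  expect_equal(unname(pseudobulk_signature(pb, c("c"), "mean")), c(1, 1, 1))
  expect_error(pseudobulk_signature(pb, c("a", "missing"), "scaled-negsum"),
               "missing")
})

test_that("scaled values (1,1,1,1) give an RPS-style score of -4", {
  # four genes whose z-scored value in one pseudo-bulk is exactly 1
  pb <- matrix(c(1, 1, 1, 1, -1, -1, -1, -1, 0, 0, 0, 0), nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  sc <- pseudobulk_signature(pb, paste0("g", 1:4), "scaled-negsum")
  expect_equal(unname(sc[1]), -4)
})

test_that("pc1 recipe recovers a planted rank-1 factor, sign-anchored", {
  set.seed(20)
  f <- rnorm(12)                       # latent per-pseudobulk factor
  load <- runif(30, 0.5, 2)            # positive loadings
  pb <- outer(load, f) + matrix(rnorm(360, sd = 0.05), 30, 12)
  dimnames(pb) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12))
  sc <- pseudobulk_signature(pb, rownames(pb), "pc1")
  expect_gt(abs(cor(sc, f)), 0.99)
  expect_gt(cor(sc, colMeans(pb)), 0)  # anchored positively to the set mean
})

test_that("packaged signature fixture parses and matches its recipes", {
  path <- system.file("extdata", "published_signatures_synthetic.gmt",
                      package = "stateatlas")
  sets <- read_gmt(path)
  expect_length(sets, 9)
  expect_setequal(sets$RPS, c("RIF1", "PARI", "RAD51", "XRCC5"))
  expect_length(sets$CIN70, 70)
  expect_length(sets$EMP, 26)
})

test_that("metastatic co-expression: printed formula and min-max scaling", {
  expect_equal(metastatic_coexpression(1, 1)$raw, 1 / sqrt(2))
  expect_equal(metastatic_coexpression(0, 1)$raw, 0)
  res <- metastatic_coexpression(c(1, 0, 2), c(1, 1, 2))
  expect_equal(res$raw, c(1 / sqrt(2), 0, sqrt(2)), tolerance = 1e-12)
  expect_equal(res$scaled, c(0.5, 0, 1), tolerance = 1e-12)
  expect_warning(z <- metastatic_coexpression(c(0, 1), c(0, 1)), "x = y = 0")
  expect_equal(z$raw[1], 0)
})
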