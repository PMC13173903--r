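# Differential expression, Fisher's combined probability, marker criteria.

test_that("subcluster_de handles degenerate genes and label symmetry", {
  set.seed(11)
  n <- 60
  expr <- matrix(abs(rnorm(5 * n)), 5, n,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:n)))
  expr[1, ] <- 1  # identical in all cells
  grp <- rep(c("A", "B"), each = n / 2)
  m <- Matrix::Matrix(expr, sparse = TRUE)
  de <- subcluster_de(m, grp)
  g1 <- de[de$gene == "g1", ]
  expect_true(all(g1$p == 1))
  expect_true(all(g1$log2fc == 0))
  a <- de[de$subcluster == "A" & de$gene == "g3", "log2fc"]
  b <- de[de$subcluster == "B" & de$gene == "g3", "log2fc"]
  expect_equal(a, -b, tolerance = 1e-12)
  expect_error(subcluster_de(m, rep("A", n)), ">= 2 subclusters")
})

test_that("vectorised Wilcoxon matches stats::wilcox.test with ties", {
  set.seed(12)
  for (i in 1:5) {
    n <- 80
    x <- matrix(rpois(4 * n, 2), 4, n,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:n)))
    grp <- rep(c("A", "B"), each = n / 2)
    de <- subcluster_de(Matrix::Matrix(x, sparse = TRUE), grp)
    for (g in rownames(x)) {
      ref <- suppressWarnings(
        wilcox.test(x[g, grp == "A"], x[g, grp == "B"],
                    exact = FALSE, correct = TRUE)$p.value)
      expect_equal(de$p[de$gene == g & de$subcluster == "A"], ref,
                   tolerance = 1e-10)
    }
  }
})

test_that("fisher_combine: identity at k=1, closed form at k=2, clamping", {
  expect_equal(fisher_combine(0.3)$combined_p, 0.3, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1, 1))$combined_p, 1)
  expect_equal(fisher_combine(c(1, 1))$chi2, 0)

  # df = 4 closed form: exp(-x/2) * (1 + x/2)
  fc <- fisher_combine(c(0.05, 0.05))
  x <- -2 * (log(0.05) + log(0.05))
  expect_equal(fc$chi2, x)
  expect_equal(fc$df, 4L)
  expect_equal(fc$combined_p, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(fc$combined_p, 0.01747866, tolerance = 1e-6)

  expect_warning(fc0 <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(fc0$combined_p > 0)
  expect_error(fisher_combine(c(0.5, 1.2)), "lie in")
})

test_that("fisher_combine agrees with numerical chi-square tail integration", {
  set.seed(13)
  for (k in 1:5) {
    p <- runif(k, 0.001, 0.999)
    fc <- fisher_combine(p)
    expect_equal(fc$combined_p, chisq_tail_numeric(fc$chi2, 2 * k),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment inside call_markers matches the textbook oracle", {
  set.seed(14)
  p <- runif(18)
  expect_equal(p.adjust(p, "BH"), bh_textbook(p), tolerance = 1e-12)
  # monotone contract: fdr >= combined p
  de <- list(s1 = data.frame(gene = paste0("g", 1:18), subcluster = "MC0",
                             p = p, log2fc = 1, n_in = 10),
             s2 = data.frame(gene = paste0("g", 1:18), subcluster = "MC0",
                             p = runif(18), log2fc = 1, n_in = 10))
  mk <- call_markers(de)
  expect_true(all(mk$table$fdr >= mk$table$combined_p - 1e-12))
  expect_equal(mk$table$rank, order(order(mk$table$combined_p)))
})

test_that("marker criteria: FDR and >= 2 fold-change-passing samples", {
  genes <- paste0("g", 1:40)
  mkde <- function(p_hit, fc_by_sample) {
    lapply(fc_by_sample, function(fc) {
      data.frame(gene = genes, subcluster = "MC0",
                 p = c(p_hit, runif(39, 0.5, 1)),
                 log2fc = c(fc, rep(0, 39)), n_in = 20)
    })
  }
  set.seed(15)
  # strong gene with FC pass in 2 of 3 samples -> marker
  de <- mkde(1e-8, list(s1 = 0.5, s2 = 0.5, s3 = 0.1))
  mk <- call_markers(de)
  row <- mk$table[mk$table$gene == "g1", ]
  expect_true(row$is_marker)
  expect_equal(row$n_samples_fc_pass, 2)
  expect_identical(mk$top$MC0, "g1")
  # same p but FC pass in only 1 sample -> not a marker
  de2 <- mkde(1e-8, list(s1 = 0.5, s2 = 0.1, s3 = 0.1))
  mk2 <- call_markers(de2)
  expect_false(mk2$table[mk2$table$gene == "g1", "is_marker"])
  expect_length(mk2$top$MC0, 0)
})

test_that("excluded gene classes never enter the marker table", {
  de <- list(s1 = data.frame(gene = c("HSPA1", "MT-CO1", "RPL13", "GENE1"),
                             subcluster = "MC0", p = rep(1e-6, 4),
                             log2fc = rep(2, 4), n_in = 10),
             s2 = data.frame(gene = c("HSPA1", "MT-CO1", "RPL13", "GENE1"),
                             subcluster = "MC0", p = rep(1e-6, 4),
                             log2fc = rep(2, 4), n_in = 10))
  mk <- call_markers(de)
  expect_identical(mk$table$gene, "GENE1")
  expect_identical(mk$top$MC0, "GENE1")
})

test_that("an MC present in a single sample yields an empty marker set", {
  de <- list(s1 = data.frame(gene = paste0("g", 1:5), subcluster = "MC0",
                             p = rep(1e-6, 5), log2fc = 2, n_in = 10))
  expect_warning(mk <- call_markers(de), "single|< 2")
  expect_length(mk$top$MC0, 0)
})

test_that("planted markers reach significance in every sample (truth recovery)", {
  co <- small_cohort()
  truth <- co$truth$cells
  st1 <- co$params$states[[1]]
  for (s in names(co$samples)[1:2]) {
    m <- co$samples[[s]]
    q <- apply_qc(m, density_gates(Matrix::colSums(m)))
    nm <- normalize_counts(q$counts)
    tr <- truth[match(colnames(q$counts), truth$barcode), ]
    de <- subcluster_de(nm$lognorm, tr$state_id,
                        genes = st1$marker_genes[1:30])
    hit <- de[de$subcluster == "S1", ]
    expect_true(all(hit$p < 0.01))
    expect_true(all(hit$log2fc > log2(1.25)))
  }
})
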