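# Synthetic-data generators: contracts, planted-truth consistency,
# determinism, and the negative-binomial count model.

test_that("generate_barnyard sizes, doublet flags and species purity", {
  b0 <- generate_barnyard(100, 100, 0, seed = 1)
  expect_equal(ncol(b0$counts), 200)
  expect_true(all(b0$truth$species %in% c("human", "mouse")))

  b <- generate_barnyard(50, 50, 0.1, seed = 1)
  expect_equal(sum(b$truth$species != "doublet"), 100)
  expect_equal(sum(b$truth$species == "doublet"), 10)
  expect_true(all(!is.na(b$truth$parent_human[b$truth$species == "doublet"])))

  # species purity of singlets recomputed by direct tally from the matrix
  is_h <- grepl("^GRCh38_", rownames(b$counts))
  h_umi <- Matrix::colSums(b$counts[is_h, ])
  tot <- Matrix::colSums(b$counts)
  purity <- ifelse(b$truth$species == "human", h_umi / tot,
                   (tot - h_umi) / tot)
  expect_true(all(purity[b$truth$species != "doublet"] >= 0.95))
  # doublets sum a human and a mouse parent's draws
  i <- which(b$truth$species == "doublet")[1]
  parents <- b$counts[, c(b$truth$parent_human[i], b$truth$parent_mouse[i])]
  expect_equal(as.numeric(b$counts[, i]), as.numeric(Matrix::rowSums(parents)))
})

test_that("generate_barnyard rejects non-positive sizes", {
  expect_error(generate_barnyard(0, 10, 0), "positive")
  expect_error(generate_barnyard(10, 10, 0.5), "doublet_rate")
})

test_that("cohort truth partitions cells; markers elevated in-state everywhere", {
  co <- small_cohort()
  tr <- co$truth$cells
  expect_equal(nrow(tr), 3 * 500)
  expect_true(all(tr$state_id %in% paste0("S", 0:4)))
  expect_true(all(tr$phase %in% c("G1", "S/G2M")))
  for (s in names(co$samples)) {
    m <- co$samples[[s]]
    t_s <- tr[tr$sample_id == s, ]
    for (st in co$params$states) {
      inn <- t_s$barcode[t_s$state_id == st$state_id]
      out <- t_s$barcode[t_s$state_id != st$state_id]
      expect_gt(mean(as.matrix(m[st$marker_genes, inn])),
                mean(as.matrix(m[st$marker_genes, out])))
    }
  }
})

test_that("cohort generation is deterministic and validates prevalences", {
  a <- generate_cohort(n_samples = 3, cells_per_sample = 60, seed = 7)
  b <- generate_cohort(n_samples = 3, cells_per_sample = 60, seed = 7)
  expect_identical(lapply(a$samples, as.matrix), lapply(b$samples, as.matrix))
  expect_identical(a$truth$cells, b$truth$cells)

  bad <- default_states(4)
  bad[[1]]$prevalence <- 0.9
  expect_error(generate_cohort(states = bad, n_samples = 3,
                               cells_per_sample = 50), "prevalence")
  expect_error(generate_cohort(n_samples = 2), "n_samples")
})

test_that("zero-effect states produce no planted marker separation", {
  co <- generate_cohort(n_samples = 3, cells_per_sample = 300,
                        states = default_states(4, 50, log2_effect = 0),
                        seed = 3)
  m <- co$samples[[1]]
  tr <- co$truth$cells[co$truth$cells$sample_id == "SAMP01", ]
  mk <- co$params$states[[1]]$marker_genes
  inn <- mean(as.matrix(m[mk, tr$barcode[tr$state_id == "S1"]]))
  out <- mean(as.matrix(m[mk, tr$barcode[tr$state_id != "S1"]]))
  expect_lt(abs(inn - out) / out, 0.15)
})

test_that("marginal counts match the configured negative binomial (chi-square GOF)", {
  # all modulation off: constant library, one zero-effect state, no cycle,
  # no mito noise -> each gene is marginally NB(mu_g, theta)
  co <- generate_cohort(
    n_samples = 3, cells_per_sample = 3500,
    states = list(state_spec("S1", character(), 0, 1)),
    batch_sd = 0, seed = 11, n_genes = 400, theta = 10,
    lib_mean = 2000, lib_sd = 0, phase_frac = 0, lowq_frac = 0,
    mito_sd = 0)
  counts <- do.call(cbind, lapply(co$samples, as.matrix))
  expect_gte(ncol(counts), 10000)
  gene <- "HK0001"
  x <- counts[gene, ]
  mu <- mean(x)  # constant conditions: plug-in mean is the model mean
  brk <- c(0:14, Inf)
  obs <- table(cut(x, breaks = c(-1, brk)))
  p <- diff(c(0, stats::pnbinom(c(brk), mu = mu, size = 10)))
  keep <- p * length(x) >= 5
  gof <- suppressWarnings(chisq.test(as.numeric(obs)[keep], p = p[keep],
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("generate_clinical plants the advertised associations", {
  expect_error(generate_clinical(50, character(), 1), "non-empty")
  expect_error(generate_clinical(10, "G1", 1), ">= 20")

  sig <- sprintf("SIG%02d", 1:30)
  resp <- generate_clinical(100, sig, effect = 1, outcome = "response",
                            seed = 2)
  sc <- colMeans(resp$expr[sig, ])
  expect_gt(mean(sc[resp$label == "RD"]) - mean(sc[resp$label == "pCR"]), 0.5)

  surv <- generate_clinical(400, sig, effect = log(2), outcome = "survival",
                            seed = 2)
  expect_lt(mean(surv$time[surv$truth$high]), mean(surv$time[!surv$truth$high]))
  expect_true(all(surv$time > 0))
})

test_that("cohort round-trips through the 10x-style MTX writer", {
  co <- generate_cohort(n_samples = 3, cells_per_sample = 50, seed = 5)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  m <- read_mtx_dir(file.path(dir, "SAMP02"))
  expect_identical(as.matrix(m), as.matrix(co$samples$SAMP02))
  tr <- read.delim(file.path(dir, "truth_cells.tsv"))
  expect_equal(nrow(tr), 150)
})

test_that("GMT files round-trip", {
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3", "g4"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
})
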