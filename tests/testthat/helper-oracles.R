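# Independent oracles and shared small fixtures for the test suite.

# Adjusted Rand index between two labelings (closed-form contingency sums).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Literal evaluation of the medoid-based Davies-Bouldin formula, written
# independently of the package implementation.
db_bruteforce <- function(d, labels) {
  d <- as.matrix(d)
  cls <- unique(labels)
  med <- sapply(cls, function(cl) {
    idx <- which(labels == cl)
    idx[which.min(sapply(idx, function(i) sum(d[i, idx])))]
  })
  sc <- sapply(seq_along(cls), function(ci) {
    idx <- which(labels == cls[ci])
    mean(sapply(idx, function(i) d[i, med[ci]]))
  })
  mean(sapply(seq_along(cls), function(i) {
    max(sapply(setdiff(seq_along(cls), i), function(j) {
      dm <- d[med[i], med[j]]
      if (dm == 0) Inf else (sc[i] + sc[j]) / dm
    }))
  }))
}

# Textbook Benjamini-Hochberg: q_i = min_{j >= i} min(1, p_(j) * m / j).
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper-tail chi-squared probability by numerical integration of the density.
chisq_tail_numeric <- function(x, df) {
  stats::integrate(function(t) stats::dchisq(t, df), lower = x, upper = Inf,
                   rel.tol = 1e-13, abs.tol = 1e-14)$value
}

# Hypergeometric upper tail by exhaustive enumeration of all draws (small N).
hyper_tail_enum <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# A small planted cohort shared by several module tests (built once).
.fixtures <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_cohort(n_samples = 3, cells_per_sample = 500,
                                       seed = 42)
  }
  .fixtures$small
}

# QC'd + normalised version of one sample of the small cohort.
small_norm <- function(sample = 1) {
  key <- paste0("norm", sample)
  if (is.null(.fixtures[[key]])) {
    co <- small_cohort()
    m <- co$samples[[sample]]
    q <- apply_qc(m, density_gates(Matrix::colSums(m)))
    .fixtures[[key]] <- normalize_counts(q$counts)
  }
  .fixtures[[key]]
}
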