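# Marker aggregation: one-vs-rest Wilcoxon differential expression within
# samples, Fisher's combined probability across samples, BH-FDR and the
# marker-calling criteria with gene-class exclusions.

# Vectorised two-sided Wilcoxon rank-sum over the rows of a genes x cells
# matrix (normal approximation with tie correction and continuity
# correction) — the workhorse for per-sample marker screens.
wilcox_rows <- function(expr, in_group) {
  expr <- as.matrix(expr)
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  p <- numeric(nrow(expr))
  for (g in seq_len(nrow(expr))) {
    x <- expr[g, ]
    r <- rank(x)
    U <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- rle(sort.int(x, method = "quick"))$lengths
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) { p[g] <- 1; next }
    z <- (U - n1 * n2 / 2)
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    p[g] <- 2 * pnorm(-abs(z))
  }
  pmin(p, 1)
}

#' One-vs-rest differential expression within a sample
#'
#' For each subcluster (the sample's cells belonging to one meta cluster),
#' tests every gene against all other cells of the sample with a two-sided
#' Wilcoxon rank-sum on log-normalised expression.  The log2 fold change is
#' the Seurat-style `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`.
#' No p or fold-change thresholding happens at this stage.
#'
#' @param lognorm sparse genes x cells log-normalised matrix for one sample.
#' @param subclusters per-cell subcluster labels aligned to `colnames`.
#' @param genes genes to test (typically the shared HVGs).
#' @param min_cells subclusters below this size are skipped (default 3).
#' @return data frame: `gene`, `subcluster`, `p`, `log2fc`, `n_in`.
#' @export
subcluster_de <- function(lognorm, subclusters, genes = rownames(lognorm),
                          min_cells = 3) {
  stopifnot(length(subclusters) == ncol(lognorm))
  genes <- intersect(genes, rownames(lognorm))
  expr <- as.matrix(lognorm[genes, , drop = FALSE])
  labs <- unique(subclusters[!is.na(subclusters)])
  if (length(labs) < 2) stopf("need >= 2 subclusters in the sample")
  res <- list()
  for (sc in labs) {
    in_group <- !is.na(subclusters) & subclusters == sc
    if (sum(in_group) < min_cells) next
    out_group <- !is.na(subclusters) & !in_group
    p <- wilcox_rows(expr[, in_group | out_group, drop = FALSE],
                     in_group[in_group | out_group])
    m_in <- rowMeans(expm1(expr[, in_group, drop = FALSE]))
    m_out <- rowMeans(expm1(expr[, out_group, drop = FALSE]))
    res[[sc]] <- data.frame(gene = genes, subcluster = sc, p = p,
                            log2fc = log2((m_in + 1) / (m_out + 1)),
                            n_in = sum(in_group), stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Fisher's combined probability test
#'
#' `chi2 = -2 * sum(log(p_i))` on `df = 2k` degrees of freedom; the combined
#' p is the upper-tail chi-squared probability.  Zero p-values are clamped to
#' the smallest positive double with a warning.
#'
#' @param p vector of per-sample p-values in `(0, 1]`.
#' @return list with `chi2`, `df`, `combined_p`.
#' @export
fisher_combine <- function(p) {
  if (!length(p)) stopf("need at least one p-value")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warnf("zero p-value clamped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi2 = chi2, df = df,
       combined_p = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Aggregate per-sample differential expression into MC marker calls
#'
#' Per meta cluster: genes of the excluded classes (heat-shock,
#' mitochondrial, RPL prefixes) are dropped; per-sample p-values are
#' combined with Fisher's method over the samples contributing to that MC;
#' combined p-values are BH-adjusted within the MC; markers require
#' `fdr < 0.01` and `log2FC > log2(1.25)` in at least 2 samples; markers are
#' ranked by combined p and the top 100 emitted.
#'
#' @param de_by_sample named list (per sample) of [subcluster_de()] results
#'   whose `subcluster` column holds MC ids.
#' @param exclude_regex character regexes of excluded gene classes.
#' @param fdr_max marker FDR threshold (default 0.01).
#' @param min_fc_samples minimum samples with passing fold change (default 2).
#' @param fc_min log2 fold-change pass threshold (default `log2(1.25)`).
#' @param top_n size of the ranked marker head list (default 100).
#' @return list with `table` (per MC x gene: `combined_p`, `fdr`,
#'   `n_samples`, `n_samples_fc_pass`, `rank`, `is_marker`) and `top`
#'   (named list of ranked marker vectors per MC).
#' @export
call_markers <- function(de_by_sample,
                         exclude_regex = c("^HSP", "^MT-", "^RPL"),
                         fdr_max = 0.01, min_fc_samples = 2,
                         fc_min = log2(1.25), top_n = 100) {
  de <- do.call(rbind, lapply(names(de_by_sample), function(s) {
    d <- de_by_sample[[s]]; d$sample_id <- s; d
  }))
  drop <- Reduce(`|`, lapply(exclude_regex, grepl, x = de$gene))
  de <- de[!drop, , drop = FALSE]
  out <- list(); top <- list()
  for (mc in sort(unique(de$subcluster))) {
    d <- de[de$subcluster == mc, , drop = FALSE]
    by_gene <- split(d, d$gene)
    tab <- do.call(rbind, lapply(by_gene, function(g) {
      fc <- fisher_combine(pmax(g$p, .Machine$double.xmin))
      data.frame(mc = mc, gene = g$gene[1], combined_p = fc$combined_p,
                 n_samples = nrow(g),
                 n_samples_fc_pass = sum(g$log2fc > fc_min),
                 stringsAsFactors = FALSE)
    }))
    tab$fdr <- p.adjust(tab$combined_p, method = "BH")
    tab$is_marker <- tab$fdr < fdr_max & tab$n_samples_fc_pass >= min_fc_samples
    tab <- tab[order(tab$combined_p, tab$gene), , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    if (max(tab$n_samples) < min_fc_samples)
      warnf("MC %s contributed by < %d samples; marker set is empty",
            mc, min_fc_samples)
    out[[mc]] <- tab
    top[[mc]] <- head(tab$gene[tab$is_marker], top_n)
  }
  list(table = do.call(rbind, out), top = top)
}
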