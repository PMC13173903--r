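# Gene-set similarity, hypergeometric enrichment, per-cell gene-set scoring
# with state assignment, pseudo-bulk signature recipes and the cosine
# metastatic co-expression score.

#' Overlap coefficient between two gene sets
#'
#' `OC(A, B) = |A intersect B| / min(|A|, |B|)`.
#'
#' @param a,b non-empty character vectors.
#' @return number in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  if (!length(a) || !length(b)) stopf("gene sets must be non-empty")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Hypergeometric (upper-tail) pathway enrichment
#'
#' For each gene set of size `K` within `[size_range]`, with `n` markers out
#' of a universe of `N` genes and an overlap of `k`, the p-value is
#' `P(X >= k)` under the hypergeometric distribution.  BH-FDR is computed
#' over the tested sets; a set is significant iff `k >= min_overlap` and
#' `fdr < fdr_max`.
#'
#' @param markers character vector of marker genes (within the universe).
#' @param sets named list of gene sets.
#' @param universe character vector of all genes, or a single integer `N`
#'   (set genes are then assumed to lie in the universe).
#' @param size_range allowed set sizes (default `c(3, 500)`).
#' @param min_overlap minimum overlap for significance (default 3).
#' @param fdr_max FDR threshold (default 0.05).
#' @return data frame with one row per tested set: `set`, `k`, `K`, `n`,
#'   `N`, `p`, `fdr`, `significant`.
#' @export
hypergeom_enrich <- function(markers, sets, universe,
                             size_range = c(3, 500), min_overlap = 3,
                             fdr_max = 0.05) {
  if (length(universe) == 1L && is.numeric(universe)) {
    N <- as.integer(universe)
    restrict <- identity
  } else {
    N <- length(unique(universe))
    markers <- intersect(markers, universe)
    restrict <- function(s) intersect(s, universe)
  }
  n <- length(unique(markers))
  rows <- lapply(names(sets), function(nm) {
    s <- unique(restrict(sets[[nm]]))
    K <- length(s)
    if (K < size_range[1] || K > size_range[2]) return(NULL)
    if (K > N) stopf("set '%s' larger than the universe", nm)
    k <- length(intersect(markers, s))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no gene set within the size range")
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$k >= min_overlap & out$fdr < fdr_max
  out[order(out$p), , drop = FALSE]
}

# Signed rank-KS enrichment of one gene set in one cell given average-tie
# ranks of all genes by decreasing expression.  Running sum steps +1/m at
# set genes and -1/(G-m) elsewhere; the score is the maximum positive
# deviation plus the maximum negative deviation of the walk (the
# max-deviation-difference convention), symmetric around 0 under
# exchangeability and bounded in [-1, 1].
rank_ks_score <- function(r, set_idx) {
  G <- length(r); m <- length(set_idx)
  rs <- sort(r[set_idx])
  i <- seq_len(m)
  pos <- max(i / m - (rs - i) / (G - m), 0)
  neg <- min((i - 1) / m - (rs - 1 - (i - 1)) / (G - m), 0)
  pos + neg
}

#' Per-cell gene-set score
#'
#' Default method `"rank-ks"`: genes are ranked by decreasing expression
#' within each cell and the score is a signed Kolmogorov-Smirnov-like
#' enrichment of the set versus non-set genes (positive when set genes
#' concentrate at the top), bounded in `[-1, 1]`.  Method `"mean-z"` is the
#' mean across set genes of per-gene z-scores.
#'
#' @param expr genes x cells expression matrix (log-normalised).
#' @param set character gene set (>= 2 genes present required).
#' @param method `"rank-ks"` (default) or `"mean-z"`.
#' @return named per-cell numeric score vector.
#' @export
score_gene_set <- function(expr, set, method = c("rank-ks", "mean-z")) {
  method <- match.arg(method)
  set <- intersect(unique(set), rownames(expr))
  if (length(set) < 2) stopf("fewer than 2 set genes present in the matrix")
  expr <- as.matrix(expr)
  if (method == "mean-z") {
    mu <- rowMeans(expr); sdv <- apply(expr, 1, sd)
    sdv[sdv == 0] <- 1
    z <- (expr[set, , drop = FALSE] - mu[set]) / sdv[set]
    return(colMeans(z))
  }
  set_idx <- match(set, rownames(expr))
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(-expr[, j])
    rank_ks_score(r, set_idx)
  }, 0)
  setNames(scores, colnames(expr))
}

#' Score several signatures per cell
#'
#' @param expr genes x cells matrix.
#' @param sets named list of gene sets.
#' @param method passed to [score_gene_set()].
#' @return cells x signatures score matrix.
#' @export
score_gene_sets <- function(expr, sets, method = "rank-ks") {
  out <- vapply(sets, function(s) score_gene_set(expr, s, method),
                numeric(ncol(expr)))
  rownames(out) <- colnames(expr)
  out
}

#' Assign cells to the state with the highest positive score
#'
#' Cells whose scores are all <= 0 are `"unassigned"`; ties break by column
#' order.
#'
#' @param scores cells x signatures matrix (columns named by MC/state).
#' @return character vector of assignments.
#' @export
assign_states <- function(scores) {
  if (is.null(dim(scores)) || ncol(scores) < 1) stopf("need >= 1 signature")
  best <- max.col(scores, ties.method = "first")
  top <- scores[cbind(seq_len(nrow(scores)), best)]
  ifelse(top > 0, colnames(scores)[best], "unassigned")
}

#' Fraction of score-positive cells per group, with a test
#'
#' Computes per subject and group the fraction of cells with score > 0, then
#' compares the two groups with a paired t-test (when `paired`) or a
#' Wilcoxon rank-sum test on per-subject fractions.
#'
#' @param scores per-cell numeric scores.
#' @param groups per-cell group labels (exactly 2 groups).
#' @param subjects per-cell subject/patient ids.
#' @param paired logical; paired t-test across subjects.
#' @return list with `fractions` (subjects x groups), `group_means`, `p`.
#' @export
positive_fraction <- function(scores, groups, subjects, paired = FALSE) {
  g <- unique(groups)
  if (length(g) != 2) stopf("need exactly 2 groups")
  tab <- tapply(scores > 0, list(subjects, groups), mean)
  if (paired) {
    ok <- complete.cases(tab)
    if (sum(ok) < 2) stopf("paired test needs >= 2 complete subjects")
    diffs <- tab[ok, g[1]] - tab[ok, g[2]]
    # identical groups give zero-variance differences: no evidence, p = 1
    p <- if (sd(diffs) == 0) 1 else t.test(diffs)$p.value
  } else {
    x <- tab[, g[1]]; y <- tab[, g[2]]
    p <- suppressWarnings(wilcox.test(x[!is.na(x)], y[!is.na(y)])$p.value)
  }
  list(fractions = tab, group_means = colMeans(tab, na.rm = TRUE), p = p)
}

#' Pseudo-bulk expression per (meta cluster, sample)
#'
#' @param lognorms named list of genes x cells log-normalised matrices.
#' @param mc_labels data frame from [mc_cell_labels()].
#' @return genes x (mc|sample) matrix of mean log-normalised expression.
#' @export
pseudobulk_profiles <- function(lognorms, mc_labels) {
  keys <- split(mc_labels, paste(mc_labels$mc, mc_labels$sample_id, sep = "|"))
  cols <- lapply(keys, function(d) {
    expr <- lognorms[[d$sample_id[1]]]
    Matrix::rowMeans(expr[, intersect(d$barcode, colnames(expr)),
                          drop = FALSE])
  })
  do.call(cbind, cols)
}

#' Published-signature recipes on pseudo-bulk expression
#'
#' * `"mean"` — mean pseudo-bulk log-normalised expression of the set
#'   (residual-tumour, prognostic, CIN70-style signatures).
#' * `"scaled-negsum"` — genes are z-scored across pseudo-bulk columns and
#'   the score is minus the sum over the set (recombination proficiency:
#'   high repair-gene expression gives a low score); every set gene must be
#'   present.
#' * `"pc1"` — first principal component of the set's pseudo-bulk
#'   expression, sign-anchored to correlate positively with the set mean.
#'
#' @param pb genes x pseudobulk matrix from [pseudobulk_profiles()].
#' @param genes signature gene set.
#' @param recipe one of `"mean"`, `"scaled-negsum"`, `"pc1"`.
#' @return named per-pseudobulk score vector.
#' @export
pseudobulk_signature <- function(pb, genes, recipe = c("mean", "scaled-negsum", "pc1")) {
  recipe <- match.arg(recipe)
  present <- intersect(unique(genes), rownames(pb))
  if (recipe == "scaled-negsum" && length(present) < length(unique(genes)))
    stopf("missing genes for scaled-negsum recipe: %s",
          paste(setdiff(unique(genes), present), collapse = ", "))
  if (!length(present)) stopf("no signature gene present in the pseudo-bulk")
  m <- pb[present, , drop = FALSE]
  switch(recipe,
    "mean" = colMeans(m),
    "scaled-negsum" = {
      z <- t(scale(t(m)))
      z[is.nan(z)] <- 0
      -colSums(z)
    },
    "pc1" = {
      pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
      s <- pc$x[, 1]
      anchor <- colMeans(m)
      if (stats::cor(s, anchor) < 0) s <- -s
      s
    })
}

#' Cell-wise cosine-style co-expression of two signature scores
#'
#' `r_i = x_i * y_i / sqrt(x_i^2 + y_i^2)`, then min-max scaled to `[0, 1]`
#' across cells.  Cells with `x = y = 0` get raw score 0 with a warning.
#'
#' @param x,y aligned per-cell score vectors.
#' @return list with `raw` and `scaled` per-cell vectors.
#' @export
metastatic_coexpression <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  denom <- sqrt(x^2 + y^2)
  r <- ifelse(denom == 0, 0, x * y / denom)
  if (any(denom == 0)) warnf("cells with x = y = 0 set to raw score 0")
  rng <- range(r)
  scaled <- if (diff(rng) > 0) (r - rng[1]) / diff(rng) else rep(0, length(r))
  list(raw = r, scaled = scaled)
}
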