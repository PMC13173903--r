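# Normalisation (regularised NB Pearson residuals with per-cell covariate
# regression), cell-cycle phase assignment, PCA elbow rule and the
# shared-nearest-neighbour graph.

#' Per-cell QC covariates used by the normalisation model
#'
#' @param counts sparse genes x cells matrix.
#' @param class_regex named regexes for mito/rpl gene classes.
#' @return data frame with `pct_mito`, `pct_rpl`, `n_genes`, `n_umi`.
#' @export
cell_covariates <- function(counts, class_regex = default_class_regex()) {
  umi <- Matrix::colSums(counts)
  frac_of <- function(rx) {
    rows <- grepl(rx, rownames(counts))
    if (!any(rows)) return(rep(0, ncol(counts)))
    Matrix::colSums(counts[rows, , drop = FALSE]) / pmax(umi, 1)
  }
  data.frame(
    pct_mito = frac_of(class_regex[["mito"]]),
    pct_rpl = frac_of(class_regex[["rpl"]]),
    n_genes = Matrix::colSums(counts > 0),
    n_umi = umi,
    row.names = colnames(counts)
  )
}

#' Normalise counts: NB Pearson residuals with covariate regression
#'
#' Computes analytic negative-binomial Pearson residuals
#' `(x - mu) / sqrt(mu + mu^2 / theta)` with `mu` the product of gene
#' abundance and cell size factor, clips them at `sqrt(n_cells)`, then
#' regresses the four per-cell covariates (mitochondrial fraction, RPL
#' fraction, genes detected, UMI total) out of every gene by least squares.
#' Highly variable genes are the top `n_hvg` by residual variance.  A
#' log-normalised layer (`log1p(counts / total * scale)`) is retained for
#' profile averaging and differential expression.
#'
#' @param counts sparse genes x cells UMI matrix (post-QC).
#' @param covariates data frame as from [cell_covariates()]; computed from
#'   `counts` when NULL.
#' @param n_hvg number of highly variable genes to flag (default 3000).
#' @param theta NB size parameter of the residual model.
#' @param scale_factor library scaling for the log layer.
#' @return object of class `sa_norm`: list with `residuals` (dense genes x
#'   cells), `lognorm` (sparse genes x cells), `hvg` (character),
#'   `covariates`.
#' @export
normalize_counts <- function(counts, covariates = NULL, n_hvg = 3000,
                             theta = 100, scale_factor = 1e4) {
  keep <- Matrix::rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (is.null(covariates)) covariates <- cell_covariates(counts)
  umi <- Matrix::colSums(counts)
  lognorm <- counts
  lognorm@x <- log1p(counts@x * rep.int(scale_factor / umi, diff(counts@p)))

  gene_tot <- Matrix::rowSums(counts)
  total <- sum(gene_tot)
  mu <- outer(gene_tot, umi) / total
  resid <- (as.matrix(counts) - mu) / sqrt(mu + mu^2 / theta)
  clip <- sqrt(ncol(counts))
  resid[resid > clip] <- clip
  resid[resid < -clip] <- -clip

  Z <- as.matrix(covariates[colnames(counts),
                            c("pct_mito", "pct_rpl", "n_genes", "n_umi")])
  Z <- Z[, apply(Z, 2, sd) > 0, drop = FALSE]  # constant covariates drop out
  X <- cbind(1, scale(Z))
  # project covariates out of every gene at once: R - R X (X'X)^-1 X'
  beta <- resid %*% X %*% solve(crossprod(X))
  resid <- resid - tcrossprod(beta, X)

  rv <- apply(resid, 1, var)
  hvg <- rownames(counts)[order(-rv)][seq_len(min(n_hvg, nrow(counts)))]
  structure(list(residuals = resid, lognorm = lognorm, hvg = hvg,
                 covariates = covariates, residual_var = rv),
            class = "sa_norm")
}

#' Assign cell-cycle phase from S and G2M programme scores
#'
#' Each programme score is the mean log-normalised expression of the set's
#' genes minus the mean of expression-matched control genes (genes binned by
#' average expression into `n_bins`, `n_ctrl` controls drawn per set gene).
#' Cells with both scores <= 0 are G1; otherwise S/G2M.
#'
#' @param nm `sa_norm` object (or a genes x cells log-expression matrix).
#' @param s_genes,g2m_genes character gene sets; defaults to
#'   [cc_gene_sets()].
#' @param n_bins,n_ctrl control-matching parameters.
#' @param seed RNG seed for control sampling.
#' @return data frame with `s_score`, `g2m_score`, `phase`
#'   (`"G1"`/`"S/G2M"`).
#' @export
assign_phase <- function(nm, s_genes = cc_gene_sets()$s,
                         g2m_genes = cc_gene_sets()$g2m,
                         n_bins = 25, n_ctrl = 50, seed = 1) {
  expr <- if (inherits(nm, "sa_norm")) nm$lognorm else nm
  genes <- rownames(expr)
  s_genes <- intersect(s_genes, genes)
  g2m_genes <- intersect(g2m_genes, genes)
  if (!length(s_genes)) stopf("no S-phase genes present in the matrix")
  if (!length(g2m_genes)) stopf("no G2M-phase genes present in the matrix")
  avg <- Matrix::rowMeans(expr)
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- genes
  score_set <- function(set) {
    ctrl <- unlist(lapply(set, function(g) {
      pool <- genes[bin == bin[[g]]]
      pool <- setdiff(pool, g)
      if (!length(pool)) return(character())
      pool[sample.int(length(pool), min(n_ctrl, length(pool)),
                      replace = length(pool) < n_ctrl)]
    }))
    Matrix::colMeans(expr[set, , drop = FALSE]) -
      Matrix::colMeans(expr[unique(ctrl), , drop = FALSE])
  }
  with_seed(seed, {
    s <- score_set(s_genes)
    g2m <- score_set(g2m_genes)
    data.frame(barcode = colnames(expr), s_score = s, g2m_score = g2m,
               phase = ifelse(pmax(s, g2m) > 0, "S/G2M", "G1"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Elbow index of an explained-variance sequence
#'
#' The first component `i` whose explained-variance percentage drops by less
#' than `tol` percentage points to component `i + 1`; when no drop is that
#' small, the last index with a warning.
#'
#' @param var_pct per-component explained-variance percentages.
#' @param tol drop threshold in percentage points (default 0.1).
#' @return integer elbow index.
#' @export
pca_elbow_index <- function(var_pct, tol = 0.1) {
  d <- -diff(var_pct)
  hit <- which(d < tol)
  if (!length(hit)) {
    warnf("no elbow found; using the last component examined")
    return(length(var_pct))
  }
  hit[1]
}

#' Choose PCA dimensionality by the consecutive-variance elbow rule
#'
#' PCA is run on the (cells x HVG) residual matrix; the retained
#' dimensionality is the first component `i` whose explained-variance
#' percentage drops by less than 0.1 percentage points to component `i + 1`.
#'
#' @param nm `sa_norm` object, or a cells x features numeric matrix.
#' @param max_pc maximum PCs to examine (default 100).
#' @param cells optional subset of cells (barcodes or indices).
#' @return list with `n_pcs`, `var_pct`, and `scores` (cells x n_pcs).
#' @export
pca_elbow <- function(nm, max_pc = 100, cells = NULL) {
  mat <- if (inherits(nm, "sa_norm")) t(nm$residuals[nm$hvg, , drop = FALSE])
  else nm
  if (!is.null(cells)) mat <- mat[cells, , drop = FALSE]
  max_pc <- min(max_pc, nrow(mat) - 1L, ncol(mat))
  if (max_pc < 3) stopf("fewer than 3 principal components computable")
  pc <- prcomp(mat, center = TRUE, scale. = FALSE, rank. = max_pc)
  var_all <- pc$sdev^2
  var_pct <- var_all / sum(var_all) * 100
  n_pcs <- pca_elbow_index(var_pct[seq_len(max_pc)])
  n_pcs <- max(n_pcs, 2L)  # a 1-D embedding defeats neighbour graphs
  list(n_pcs = n_pcs, var_pct = var_pct[seq_len(max_pc)],
       scores = pc$x[, seq_len(n_pcs), drop = FALSE])
}

#' Build a shared-nearest-neighbour similarity graph
#'
#' k-nearest neighbours (Euclidean, self included) in PC space; edge weight
#' is the Jaccard overlap of neighbour lists, min-max scaled to `[0, 1]`.
#'
#' @param pcs cells x n_pcs embedding.
#' @param k neighbourhood size (default 20).
#' @return object of class `sa_snn`: list with sparse symmetric `snn`
#'   (unit diagonal) and `k`.
#' @export
build_snn <- function(pcs, k = 20) {
  n <- nrow(pcs)
  if (k >= n) stopf("k = %d must be smaller than the number of cells (%d)", k, n)
  if (ncol(pcs) < 2) stopf("need at least 2 dimensions")
  d <- as.matrix(dist(pcs))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  A <- sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
                    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  snn <- shared
  snn@x <- shared@x / (2 * k - shared@x)  # Jaccard: |I| / (|A|+|B|-|I|)
  rng <- c(min(0, snn@x), max(snn@x))  # implicit zeros are true minima
  if (diff(rng) > 0) snn@x <- (snn@x - rng[1]) / (rng[2] - rng[1])
  dimnames(snn) <- list(rownames(pcs), rownames(pcs))
  structure(list(snn = methods::as(snn, "CsparseMatrix"), k = k),
            class = "sa_snn")
}
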