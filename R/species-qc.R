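# Species assignment, density-derived QC gates, doublet consensus rule and
# matrix filtering for barnyard (PDX human/mouse) nuclei.

#' Assign nuclei to species by dual-genome UMI thresholds
#'
#' Thresholds are the 10th percentile (linear-interpolation quantile) of each
#' species' UMI counts over the nuclei where that species dominates.  A
#' nucleus is called human iff its human UMIs exceed the human threshold, its
#' mouse UMIs fall below the mouse threshold, and human exceeds mouse; all
#' other nuclei are excluded.
#'
#' @param human_umi,mouse_umi aligned per-cell UMI count vectors.
#' @return list with `labels` (character, `"human"`/`"excluded"`) and
#'   `thresholds` (`t_human`, `t_mouse`).
#' @export
call_species <- function(human_umi, mouse_umi) {
  if (length(human_umi) != length(mouse_umi))
    stopf("human_umi and mouse_umi must have equal length")
  h_major <- human_umi > mouse_umi
  m_major <- mouse_umi > human_umi
  if (!any(h_major)) {
    warnf("no human-majority nuclei; human threshold set to 0")
    t_h <- 0
  } else t_h <- unname(quantile(human_umi[h_major], 0.10, type = 7))
  if (!any(m_major)) {
    warnf("no mouse-majority nuclei; mouse threshold set to +Inf")
    t_m <- Inf
  } else t_m <- unname(quantile(mouse_umi[m_major], 0.10, type = 7))
  labels <- ifelse(human_umi > t_h & mouse_umi < t_m & human_umi > mouse_umi,
                   "human", "excluded")
  list(labels = labels, thresholds = list(t_human = t_h, t_mouse = t_m))
}

#' Derive low/high QC gates from density local minima
#'
#' A Gaussian KDE (Silverman bandwidth, 512-point grid) is fitted on
#' `log10(values + 1)`.  The low gate is the left-most local minimum below
#' the global mode and the high gate the right-most local minimum above it;
#' a side without a local minimum passes through to the data extreme.
#'
#' @param values per-cell counts (reads or UMIs); >= 100 cells required.
#' @return numeric `c(low, high)` on the original count scale.
#' @export
density_gates <- function(values) {
  if (length(values) < 100) stopf("density_gates needs >= 100 cells")
  if (diff(range(values)) == 0) {
    warnf("constant input; gates pass through")
    return(c(low = min(values), high = max(values)))
  }
  x <- log10(values + 1)
  d <- density(x, bw = "nrd0", n = 512)
  y <- d$y
  mins <- which(diff(sign(diff(y))) == 2) + 1L
  mode_i <- which.max(y)
  low_i <- mins[mins < mode_i]
  high_i <- mins[mins > mode_i]
  low <- if (length(low_i)) 10^d$x[min(low_i)] - 1 else min(values)
  high <- if (length(high_i)) 10^d$x[max(high_i)] - 1 else max(values)
  c(low = low, high = high)
}

#' Consensus doublet removal from two callers
#'
#' Removes the intersection of both callers' calls; when the intersection
#' exceeds the expected doublet count, only the `n_expected` intersecting
#' barcodes with the highest primary scores are removed (ties broken by
#' barcode lexicographic order).
#'
#' @param barcodes cell barcodes.
#' @param scores_primary per-cell primary doublet scores (higher = more
#'   doublet-like).
#' @param calls_primary,calls_secondary logical per-cell calls.
#' @param n_expected expected number of doublets (>= 0).
#' @return character vector of barcodes to remove.
#' @export
consensus_doublets <- function(barcodes, scores_primary, calls_primary,
                               calls_secondary, n_expected) {
  n <- length(barcodes)
  if (length(scores_primary) != n || length(calls_primary) != n ||
      length(calls_secondary) != n)
    stopf("all inputs must align to the same barcodes")
  if (any(!is.finite(scores_primary))) stopf("scores must be finite")
  if (n_expected < 0) stopf("n_expected must be >= 0")
  inter <- which(calls_primary & calls_secondary)
  if (length(inter) <= n_expected) return(sort(barcodes[inter]))
  ord <- inter[order(-scores_primary[inter], barcodes[inter])]
  sort(barcodes[ord[seq_len(n_expected)]])
}

#' Apply QC gates and the gene-detection filter to a count matrix
#'
#' Retains cells whose UMI totals (and read totals, when supplied) fall
#' within the inclusive `[low, high]` gates and whose mitochondrial UMI
#' fraction is strictly below `mito_max`; then keeps genes detected in at
#' least `min_cells` retained cells.
#'
#' @param counts sparse genes x cells UMI matrix.
#' @param umi_gates numeric `c(low, high)` for UMI totals, e.g. from
#'   [density_gates()].
#' @param mito_genes character vector (or regex via `mito_regex`) of
#'   mitochondrial genes.
#' @param reads optional per-cell read counts with `read_gates`.
#' @param read_gates optional `c(low, high)` for reads.
#' @param mito_max maximum mitochondrial fraction (strict `<`), default 0.05.
#' @param min_cells minimum cells a gene must be detected in (default 5).
#' @param mito_regex used when `mito_genes` is NULL (default `"^MT-"`).
#' @return list with filtered `counts` and a per-cell `log` data frame of
#'   pass/fail flags.
#' @export
apply_qc <- function(counts, umi_gates, mito_genes = NULL, reads = NULL,
                     read_gates = NULL, mito_max = 0.05, min_cells = 5,
                     mito_regex = "^MT-") {
  if (is.null(mito_genes))
    mito_genes <- grep(mito_regex, rownames(counts), value = TRUE)
  umi <- Matrix::colSums(counts)
  mito_frac <- if (length(mito_genes))
    Matrix::colSums(counts[rownames(counts) %in% mito_genes, , drop = FALSE]) /
      pmax(umi, 1)
  else rep(0, ncol(counts))
  pass_umi <- umi >= umi_gates[1] & umi <= umi_gates[2]
  pass_reads <- if (!is.null(reads)) {
    if (is.null(read_gates)) stopf("reads supplied without read_gates")
    reads >= read_gates[1] & reads <= read_gates[2]
  } else rep(TRUE, ncol(counts))
  pass_mito <- mito_frac < mito_max
  keep <- pass_umi & pass_reads & pass_mito
  log <- data.frame(barcode = colnames(counts), n_umi = umi,
                    mito_frac = mito_frac, pass_umi = pass_umi,
                    pass_reads = pass_reads, pass_mito = pass_mito,
                    keep = keep, stringsAsFactors = FALSE)
  if (!any(keep))
    stopf("all cells fail QC (umi pass: %d, reads pass: %d, mito pass: %d)",
          sum(pass_umi), sum(pass_reads), sum(pass_mito))
  out <- counts[, keep, drop = FALSE]
  detected <- Matrix::rowSums(out > 0)
  out <- out[detected >= min_cells, , drop = FALSE]
  list(counts = out, log = log)
}

#' Per-sample QC summary table
#'
#' Mirrors the fields of a per-sample QC report: raw cells, thresholds,
#' retained cells.
#'
#' @param qc result of [apply_qc()].
#' @param sample_id sample label.
#' @param umi_gates the gates that were applied.
#' @return one-row data frame.
#' @export
qc_report <- function(qc, sample_id, umi_gates) {
  data.frame(sample_id = sample_id, raw_cells = nrow(qc$log),
             umi_low = umi_gates[1], umi_high = umi_gates[2],
             retained_cells = sum(qc$log$keep),
             retained_genes = nrow(qc$counts), stringsAsFactors = FALSE)
}
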