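# Regulon activity scoring (AUCell-style recovery-curve AUC) and
# meta-cluster-specific transcription-factor calling.

#' AUCell-style per-cell regulon activity
#'
#' Genes are ranked per cell by decreasing expression (ties broken randomly
#' under a fixed seed).  Activity is the area under the recovery curve of
#' regulon genes within the top `top_frac` of ranks, normalised by the
#' maximal achievable area, giving values in `[0, 1]`.
#'
#' @param expr genes x cells expression matrix.
#' @param regulon character gene set (>= 2 genes present required).
#' @param top_frac fraction of top-ranked genes integrated over, in
#'   `(0, 0.5]` (default 0.05).
#' @param seed RNG seed for random tie-breaking.
#' @return named per-cell activity vector.
#' @export
aucell_score <- function(expr, regulon, top_frac = 0.05, seed = 1) {
  if (top_frac <= 0 || top_frac > 0.5) stopf("top_frac must lie in (0, 0.5]")
  regulon <- intersect(unique(regulon), rownames(expr))
  if (length(regulon) < 2) stopf("fewer than 2 regulon genes in the matrix")
  expr <- as.matrix(expr)
  G <- nrow(expr)
  n_top <- max(1L, floor(top_frac * G))
  ridx <- match(regulon, rownames(expr))
  R <- length(ridx)
  max_auc <- sum(pmin(seq_len(n_top), R))
  with_seed(seed, {
    scores <- vapply(seq_len(ncol(expr)), function(j) {
      r <- rank(-expr[, j], ties.method = "random")
      rr <- r[ridx]
      rr <- rr[rr <= n_top]
      if (!length(rr)) return(0)
      # recovery curve: at rank i the curve height is #{regulon ranks <= i}
      auc <- sum(n_top - rr + 1L)
      auc / max_auc
    }, 0)
    setNames(scores, colnames(expr))
  })
}

#' Score several regulons per cell
#'
#' @param expr genes x cells matrix.
#' @param regulons named list of gene sets.
#' @param top_frac,seed passed to [aucell_score()].
#' @return cells x regulons activity matrix.
#' @export
aucell_matrix <- function(expr, regulons, top_frac = 0.05, seed = 1) {
  out <- vapply(regulons, function(rg) aucell_score(expr, rg, top_frac, seed),
                numeric(ncol(expr)))
  rownames(out) <- colnames(expr)
  out
}

#' Call meta-cluster-specific transcription factors
#'
#' Per sample, per TF, per MC: a Wilcoxon rank-sum test of activity in the
#' target MC versus all other cells of the sample.  A TF passes in a sample
#' iff `p < 0.05` and the mean activity difference exceeds `diff_min`.  A TF
#' is a candidate for an MC iff it passes in at least `min_pass_samples`
#' samples, its regulon is detected (non-zero activity) in at least
#' `min_detect_samples` samples, and its pooled median activity is higher in
#' the target MC than in the rest.  A TF is *specific* iff it is a candidate
#' for exactly one MC.
#'
#' @param activity cells x TF activity matrix.
#' @param mc per-cell MC labels.
#' @param sample_id per-cell sample labels.
#' @param diff_min mean-difference threshold (default 0.1).
#' @param p_max per-sample significance threshold (default 0.05).
#' @param min_pass_samples,min_detect_samples candidate criteria (1 and 2).
#' @return list with `table` (per TF x MC: `n_pass`, `n_detected`,
#'   `median_in`, `median_out`, `candidate`) and `specific` (named character:
#'   TF -> MC).
#' @export
mc_specific_tfs <- function(activity, mc, sample_id, diff_min = 0.1,
                            p_max = 0.05, min_pass_samples = 1,
                            min_detect_samples = 2) {
  stopifnot(nrow(activity) == length(mc), length(mc) == length(sample_id))
  tfs <- colnames(activity)
  mcs <- sort(unique(mc))
  samples <- unique(sample_id)
  rows <- list()
  for (tf in tfs) {
    act <- activity[, tf]
    n_detected <- sum(vapply(samples, function(s)
      any(act[sample_id == s] > 0), TRUE))
    if (n_detected == 0) next
    for (m in mcs) {
      n_pass <- 0L
      for (s in samples) {
        sel <- sample_id == s
        a_in <- act[sel & mc == m]; a_out <- act[sel & mc != m]
        if (length(a_in) < 2 || length(a_out) < 2) next
        p <- suppressWarnings(wilcox.test(a_in, a_out)$p.value)
        if (!is.na(p) && p < p_max && mean(a_in) - mean(a_out) > diff_min)
          n_pass <- n_pass + 1L
      }
      med_in <- median(act[mc == m]); med_out <- median(act[mc != m])
      rows[[paste(tf, m)]] <- data.frame(
        tf = tf, mc = m, n_pass = n_pass, n_detected = n_detected,
        median_in = med_in, median_out = med_out,
        candidate = n_pass >= min_pass_samples &
          n_detected >= min_detect_samples & med_in > med_out,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  specific <- character()
  if (!is.null(tab)) {
    for (tf in unique(tab$tf)) {
      cand <- tab$mc[tab$tf == tf & tab$candidate]
      if (length(cand) == 1) specific[tf] <- cand
    }
  }
  list(table = tab, specific = specific)
}

#' Overlap coefficients of regulons against MC marker heads, with a t-test
#'
#' For each TF, the overlap coefficient of its regulon with every MC's
#' top-marker list; per target MC, a one-sample t-test asks whether the
#' other MCs' OC values fall below the target's OC (flagged at `p < 0.05`).
#' With fewer than 2 other MCs, or degenerate OC values, the p-value is
#' undefined (`NA`).
#'
#' @param regulons named list of TF target-gene sets.
#' @param top_markers named list of per-MC marker vectors (e.g. the `top`
#'   element of [call_markers()]).
#' @return data frame per (TF, MC): `oc`, `p`, `flag`.
#' @export
oc_vs_markers <- function(regulons, top_markers) {
  mcs <- names(top_markers)
  rows <- list()
  for (tf in names(regulons)) {
    oc <- vapply(mcs, function(m)
      overlap_coefficient(regulons[[tf]], top_markers[[m]]), 0)
    for (m in mcs) {
      others <- oc[setdiff(mcs, m)]
      p <- if (length(others) >= 2 && sd(others) > 0)
        t.test(others, mu = oc[[m]], alternative = "less")$p.value
      else NA_real_
      rows[[paste(tf, m)]] <- data.frame(tf = tf, mc = m, oc = oc[[m]], p = p,
                                         flag = !is.na(p) && p < 0.05,
                                         stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
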