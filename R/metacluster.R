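# Meta clustering: merge per-sample initial clusters across samples via
# Spearman similarity of mean log-expression profiles over shared HVGs and
# an average-linkage hierarchical cut at similarity 0.75.

#' Genes variable in at least `min_support` samples
#'
#' @param hvg_lists named list of per-sample HVG character vectors.
#' @param min_support minimum number of supporting samples (default 3).
#' @return list with `genes` and named `support` counts.
#' @export
shared_hvgs <- function(hvg_lists, min_support = 3) {
  if (length(hvg_lists) < min_support)
    stopf("need >= %d samples for min_support = %d", min_support, min_support)
  tab <- table(unlist(lapply(hvg_lists, unique)))
  genes <- names(tab)[tab >= min_support]
  if (!length(genes))
    stopf("no gene is variable in >= %d samples; lower min_support", min_support)
  list(genes = genes, support = as.integer(tab[genes]))
}

#' Mean log-expression profiles of initial clusters over shared HVGs
#'
#' @param lognorms named list of sparse genes x cells log-normalised matrices
#'   (one per sample, e.g. the `lognorm` layer of [normalize_counts()]).
#' @param labelings list of labelings from [cluster_all()].
#' @param genes shared HVG set (from [shared_hvgs()]).
#' @param min_cells clusters below this size are excluded with a warning.
#' @return genes x clusters profile matrix; columns named
#'   `"sample|phase|cluster"`, with cluster sizes in
#'   `attr(, "sizes")`.
#' @export
cluster_profiles <- function(lognorms, labelings, genes, min_cells = 3) {
  cols <- list(); sizes <- integer()
  for (lb in labelings) {
    expr <- lognorms[[lb$sample_id]]
    g <- intersect(genes, rownames(expr))
    for (cl in sort(unique(lb$labels))) {
      cells <- lb$barcodes[lb$labels == cl]
      id <- paste(lb$sample_id, lb$phase, cl, sep = "|")
      if (length(cells) < min_cells) {
        warnf("excluding %s: only %d cells", id, length(cells))
        next
      }
      prof <- Matrix::rowMeans(expr[g, cells, drop = FALSE])
      full <- setNames(rep(NA_real_, length(genes)), genes)
      full[g] <- prof
      cols[[id]] <- full
      sizes[id] <- length(cells)
    }
  }
  if (!length(cols)) stopf("no clusters with >= %d cells", min_cells)
  out <- do.call(cbind, cols)
  rownames(out) <- genes
  attr(out, "sizes") <- sizes
  out
}

#' Pairwise Spearman similarity between cluster profiles
#'
#' @param profiles genes x clusters matrix from [cluster_profiles()].
#' @return symmetric matrix of Spearman rank correlations (average-rank
#'   ties); a constant profile correlates 0 with everything (warning).
#' @export
intercluster_similarity <- function(profiles) {
  if (ncol(profiles) < 2) stopf("need >= 2 profiles")
  if (nrow(profiles) < 3) stopf("need >= 3 genes")
  suppressWarnings(s <- cor(profiles, method = "spearman",
                            use = "pairwise.complete.obs"))
  if (anyNA(s)) {
    warnf("constant profile(s); undefined correlations set to 0")
    s[is.na(s)] <- 0
    diag(s) <- 1
  }
  s
}

#' Cut meta clusters from the inter-cluster similarity matrix
#'
#' Average-linkage hierarchical clustering on distance `1 - rho`, cut at
#' height `1 - cutoff` so clusters merge while their similarity stays at or
#' above the cutoff.  Meta clusters are renamed `MC0..MCk` by decreasing
#' total cell count.
#'
#' @param sim symmetric similarity matrix.
#' @param cutoff similarity cutoff (default 0.75).
#' @param sizes named per-initial-cluster cell counts (used for MC naming);
#'   defaults to equal sizes.
#' @return list with `assignment` (data frame: `initial_cluster`, `mc`),
#'   `hclust` (the tree), `n_mc`.
#' @export
cut_meta_clusters <- function(sim, cutoff = 0.75, sizes = NULL) {
  if (nrow(sim) != ncol(sim) || max(abs(sim - t(sim))) > 1e-8)
    stopf("similarity matrix must be square and symmetric")
  ids <- colnames(sim)
  if (nrow(sim) == 1L) {
    return(list(assignment = data.frame(initial_cluster = ids, mc = "MC0",
                                        stringsAsFactors = FALSE),
                hclust = NULL, n_mc = 1L))
  }
  hc <- hclust(as.dist(1 - sim), method = "average")
  grp <- cutree(hc, h = 1 - cutoff)
  if (is.null(sizes)) sizes <- setNames(rep(1L, length(ids)), ids)
  tot <- tapply(sizes[ids], grp, sum)
  mc_rank <- rank(-tot, ties.method = "first")
  mc <- paste0("MC", mc_rank[as.character(grp)] - 1L)
  list(assignment = data.frame(initial_cluster = ids, mc = mc,
                               stringsAsFactors = FALSE),
       hclust = hc, n_mc = length(unique(mc)))
}

#' Per-cell meta-cluster labels from an assignment
#'
#' @param labelings list from [cluster_all()].
#' @param assignment data frame from [cut_meta_clusters()].
#' @return data frame with `barcode`, `sample_id`, `phase`, `mc`.
#' @export
mc_cell_labels <- function(labelings, assignment) {
  map <- setNames(assignment$mc, assignment$initial_cluster)
  do.call(rbind, lapply(labelings, function(lb) {
    ids <- paste(lb$sample_id, lb$phase, lb$labels, sep = "|")
    data.frame(barcode = lb$barcodes, sample_id = lb$sample_id,
               phase = lb$phase, mc = unname(map[ids]),
               stringsAsFactors = FALSE)
  }))
}
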