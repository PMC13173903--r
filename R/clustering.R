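# Within-sample clustering: modularity community detection on the SNN graph
# with the community-detection resolution chosen by minimising a medoid-based
# Davies-Bouldin index over a fixed grid, constrained to 3-8 clusters.

#' Medoid-based Davies-Bouldin index on a distance matrix
#'
#' Per-cluster scatter is the mean distance of members to the cluster medoid
#' (the member minimising total within-cluster distance; ties broken by first
#' index).  The index is the mean over clusters of
#' `max_{j != i} (scatter_i + scatter_j) / d(medoid_i, medoid_j)`; lower is
#' better.  Coincident medoids of distinct clusters make that pairwise term
#' infinite (with a warning).
#'
#' @param dist_mat square symmetric distance matrix.
#' @param labels cluster labels (>= 2 clusters).
#' @return the index (a single number).
#' @export
davies_bouldin <- function(dist_mat, labels) {
  dist_mat <- as.matrix(dist_mat)
  labels <- as.character(labels)
  cl <- unique(labels)
  if (length(cl) < 2) stopf("davies_bouldin needs >= 2 clusters")
  medoid <- integer(length(cl)); scatter <- numeric(length(cl))
  for (i in seq_along(cl)) {
    idx <- which(labels == cl[i])
    tot <- rowSums(dist_mat[idx, idx, drop = FALSE])
    medoid[i] <- idx[which.min(tot)]
    scatter[i] <- mean(dist_mat[idx, medoid[i]])
  }
  md <- dist_mat[medoid, medoid, drop = FALSE]
  if (any(md[upper.tri(md)] == 0))
    warnf("coincident medoids of distinct clusters; treating term as +Inf")
  per_cluster <- vapply(seq_along(cl), function(i) {
    r <- (scatter[i] + scatter[-i]) / md[i, -i]
    r[md[i, -i] == 0] <- Inf
    max(r)
  }, 0)
  mean(per_cluster)
}

#' Default resolution search grid
#' @return numeric vector `{0.01..0.1 by 0.01} U {0.2..1 by 0.05}`.
#' @export
resolution_grid <- function() c(seq(0.01, 0.1, by = 0.01), seq(0.2, 1, by = 0.05))

#' Select a clustering resolution by minimising the Davies-Bouldin index
#'
#' Runs Louvain modularity clustering on the SNN graph at every grid
#' resolution; among resolutions yielding 3-8 clusters, returns the labelling
#' with the lowest Davies-Bouldin index computed on distance
#' `1 - scaled SNN similarity` (ties broken by the lowest resolution).  If no
#' resolution is feasible, falls back (with a warning) to the resolution
#' whose cluster count is nearest the 3-8 range.
#'
#' @param snn `sa_snn` object from [build_snn()].
#' @param grid resolutions to scan.
#' @param n_range allowed cluster-count range.
#' @param seed RNG seed for the community detection.
#' @return list with `labels` (integer, dense `0..n-1`), `resolution`,
#'   `db_index`, `n_clusters`.
#' @export
select_resolution <- function(snn, grid = resolution_grid(),
                              n_range = c(3L, 8L), seed = 1) {
  stopifnot(inherits(snn, "sa_snn"))
  s <- snn$snn
  g <- igraph::graph_from_adjacency_matrix(s, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  dist_mat <- 1 - as.matrix(s)
  diag(dist_mat) <- 0
  runs <- lapply(grid, function(res) {
    memb <- with_seed(seed, igraph::membership(
      igraph::cluster_louvain(g, resolution = res)))
    labels <- as.integer(factor(memb)) - 1L
    list(resolution = res, labels = labels,
         n_clusters = length(unique(labels)))
  })
  ncl <- vapply(runs, `[[`, 0L, "n_clusters")
  feasible <- which(ncl >= n_range[1] & ncl <= n_range[2] &
                      vapply(runs, function(r) min(table(r$labels)) >= 2, TRUE))
  if (length(feasible)) {
    db <- vapply(feasible, function(i)
      davies_bouldin(dist_mat, runs[[i]]$labels), 0)
    best <- feasible[order(db, grid[feasible])[1]]
    db_best <- db[order(db, grid[feasible])[1]]
  } else {
    warnf("no grid resolution yields %d-%d clusters; falling back to nearest",
          n_range[1], n_range[2])
    gap <- pmax(n_range[1] - ncl, ncl - n_range[2], 0)
    best <- order(gap, grid)[1]
    db_best <- if (runs[[best]]$n_clusters >= 2 &&
                   min(table(runs[[best]]$labels)) >= 2)
      davies_bouldin(dist_mat, runs[[best]]$labels) else NA_real_
  }
  r <- runs[[best]]
  list(labels = r$labels, resolution = r$resolution, db_index = db_best,
       n_clusters = r$n_clusters)
}

#' Cluster every (sample, phase) stratum
#'
#' For each sample and phase with at least `min_cells` cells: PCA elbow,
#' SNN graph, resolution selection.  Smaller strata are skipped with a
#' warning.
#'
#' @param norms named list of `sa_norm` objects, one per sample.
#' @param phases named list of phase assignment data frames (from
#'   [assign_phase()]), aligned with `norms`.
#' @param min_cells minimum stratum size (default 50).
#' @param k SNN neighbourhood size.
#' @param max_pc maximum PCs for the elbow rule.
#' @param grid resolution grid.
#' @param seed RNG seed.
#' @return list of labelings; each has `sample_id`, `phase`, `barcodes`,
#'   `labels`, `resolution`, `db_index`, `n_clusters`.
#' @export
cluster_all <- function(norms, phases, min_cells = 50, k = 20, max_pc = 100,
                        grid = resolution_grid(), seed = 1) {
  out <- list()
  for (s in names(norms)) {
    ph <- phases[[s]]
    for (p in c("G1", "S/G2M")) {
      cells <- ph$barcode[ph$phase == p]
      if (length(cells) < min_cells) {
        warnf("skipping %s / %s: only %d cells", s, p, length(cells))
        next
      }
      pc <- pca_elbow(norms[[s]], max_pc = max_pc, cells = cells)
      snn <- build_snn(pc$scores, k = k)
      sel <- select_resolution(snn, grid = grid, seed = seed)
      out[[paste(s, p, sep = "|")]] <- c(
        list(sample_id = s, phase = p, barcodes = cells, n_pcs = pc$n_pcs),
        sel)
    }
  }
  out
}
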