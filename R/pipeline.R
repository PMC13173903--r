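# Orchestrator: wires simulate -> qc -> preprocess -> per-phase clustering ->
# meta clustering -> markers -> signature scoring into one resumable run
# directory with a JSON manifest.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline stages in one list; override any element
#' before passing to [run_pipeline()].
#'
#' @return nested named list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1,
    simulate = list(n_samples = 5, cells_per_sample = 2000, n_states = 4,
                    markers_per_state = 150, log2_effect = 2,
                    batch_sd = 0.2),
    qc = list(mito_max = 0.05, min_cells_per_gene = 5),
    preprocess = list(n_hvg = 3000, k = 20, max_pc = 100),
    cluster = list(min_cells = 50),
    metacluster = list(min_support = 3, cutoff = 0.75),
    markers = list(fdr_max = 0.01, min_fc_samples = 2, top_n = 100),
    score = list(method = "rank-ks")
  )
}

run_stage <- function(dir, name, resume, fun) {
  path <- file.path(dir, paste0(name, ".rds"))
  if (resume && file.exists(path)) return(readRDS(path))
  value <- fun()
  saveRDS(value, path)
  value
}

#' Run the full synthetic end-to-end pipeline
#'
#' Stages: simulate, per-sample QC, normalisation, phase assignment,
#' per-(sample, phase) clustering, per-phase meta clustering, marker
#' aggregation, signature scoring with state assignment.  Each stage's
#' result is cached as an RDS file under `out_dir`; with `resume = TRUE`
#' (default) existing stage outputs are reused, so deleting one stage file
#' re-executes only it and everything downstream of it on the next call.
#' A `manifest.json` records parameters and stage files.
#'
#' @param config list as from [default_config()].
#' @param out_dir run directory (created if needed).
#' @param resume reuse existing stage outputs (default TRUE).
#' @return invisible list with all stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         resume = TRUE) {
  stopifnot(is.list(config), is.numeric(config$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- run_stage(out_dir, "01_simulate", resume, function() {
    sim <- config$simulate
    generate_cohort(n_samples = sim$n_samples,
                    states = default_states(sim$n_states,
                                            sim$markers_per_state,
                                            sim$log2_effect),
                    cells_per_sample = sim$cells_per_sample,
                    batch_sd = sim$batch_sd, seed = config$seed)
  })

  qc <- run_stage(out_dir, "02_qc", resume, function() {
    lapply(cohort$samples, function(m) {
      gates <- density_gates(Matrix::colSums(m))
      apply_qc(m, gates, mito_max = config$qc$mito_max,
               min_cells = config$qc$min_cells_per_gene)
    })
  })

  norms <- run_stage(out_dir, "03_normalize", resume, function() {
    lapply(qc, function(q) normalize_counts(q$counts,
                                            n_hvg = config$preprocess$n_hvg))
  })

  phases <- run_stage(out_dir, "04_phase", resume, function() {
    lapply(norms, assign_phase, seed = config$seed)
  })

  labelings <- run_stage(out_dir, "05_cluster", resume, function() {
    cluster_all(norms, phases, min_cells = config$cluster$min_cells,
                k = config$preprocess$k, max_pc = config$preprocess$max_pc,
                seed = config$seed)
  })

  meta <- run_stage(out_dir, "06_metacluster", resume, function() {
    hvgs <- shared_hvgs(lapply(norms, `[[`, "hvg"),
                        min_support = config$metacluster$min_support)
    lognorms <- lapply(norms, `[[`, "lognorm")
    per_phase <- lapply(c(G1 = "G1", `S/G2M` = "S/G2M"), function(p) {
      lbs <- Filter(function(lb) lb$phase == p, labelings)
      if (!length(lbs)) return(NULL)
      prof <- cluster_profiles(lognorms, lbs, hvgs$genes)
      sim <- intercluster_similarity(prof)
      cut <- cut_meta_clusters(sim, cutoff = config$metacluster$cutoff,
                               sizes = attr(prof, "sizes"))
      cut$cells <- mc_cell_labels(lbs, cut$assignment)
      cut$similarity <- sim
      cut
    })
    list(hvgs = hvgs, per_phase = per_phase)
  })

  markers <- run_stage(out_dir, "07_markers", resume, function() {
    lognorms <- lapply(norms, `[[`, "lognorm")
    lapply(meta$per_phase, function(ph) {
      if (is.null(ph)) return(NULL)
      de <- lapply(names(lognorms), function(s) {
        cells <- ph$cells[ph$cells$sample_id == s, ]
        if (length(unique(cells$mc)) < 2) return(NULL)
        expr <- lognorms[[s]][, cells$barcode, drop = FALSE]
        subcluster_de(expr, cells$mc, genes = meta$hvgs$genes)
      })
      names(de) <- names(lognorms)
      call_markers(Filter(Negate(is.null), de),
                   fdr_max = config$markers$fdr_max,
                   min_fc_samples = config$markers$min_fc_samples,
                   top_n = config$markers$top_n)
    })
  })

  scores <- run_stage(out_dir, "08_score", resume, function() {
    lognorms <- lapply(norms, `[[`, "lognorm")
    lapply(names(markers), function(p) {
      mk <- markers[[p]]
      if (is.null(mk) || !length(mk$top)) return(NULL)
      sets <- Filter(function(g) length(g) >= 2, mk$top)
      if (!length(sets)) return(NULL)
      cells <- meta$per_phase[[p]]$cells
      per_sample <- lapply(names(lognorms), function(s) {
        bc <- cells$barcode[cells$sample_id == s]
        if (!length(bc)) return(NULL)
        score_gene_sets(lognorms[[s]][, bc, drop = FALSE], sets,
                        method = config$score$method)
      })
      sc <- do.call(rbind, Filter(Negate(is.null), per_sample))
      list(scores = sc, state = assign_states(sc))
    })
  })
  names(scores) <- names(markers)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = config,
    stages = list.files(out_dir, pattern = "\\.rds$")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, qc = qc, norms = norms, phases = phases,
                 labelings = labelings, meta = meta, markers = markers,
                 scores = scores, out_dir = out_dir))
}
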