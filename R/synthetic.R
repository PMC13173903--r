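# Synthetic-data module: generates every input the pipeline consumes with
# planted ground truth.  Counts follow a negative-binomial model around
# gene-level baselines modulated by state, batch, cell-cycle and
# mitochondrial-content factors; see the methods vignette for the rationale
# behind each default.

#' Specify a planted transcriptional state
#'
#' @param state_id character label.
#' @param marker_genes character vector of genes over-expressed in-state.
#' @param log2_effect positive log2 fold-change applied to `marker_genes` in
#'   cells of this state.
#' @param prevalence expected fraction of cells per sample in `[0, 1]`.
#' @return a `state_spec` list.
#' @export
state_spec <- function(state_id, marker_genes, log2_effect, prevalence) {
  if (!is.character(state_id) || length(state_id) != 1L)
    stopf("`state_id` must be a single string")
  if (length(marker_genes) < 1L && log2_effect > 0)
    stopf("state '%s': marker_genes must be non-empty when log2_effect > 0", state_id)
  assert_scalar_num(log2_effect, "log2_effect", lower = 0)
  assert_scalar_num(prevalence, "prevalence", lower = 0, upper = 1)
  structure(list(state_id = state_id, marker_genes = as.character(marker_genes),
                 log2_effect = log2_effect, prevalence = prevalence),
            class = "state_spec")
}

validate_states <- function(states) {
  if (!length(states)) stopf("need at least one state spec")
  ids <- vapply(states, `[[`, "", "state_id")
  if (anyDuplicated(ids)) stopf("duplicate state ids")
  all_markers <- unlist(lapply(states, `[[`, "marker_genes"))
  if (anyDuplicated(all_markers))
    stopf("marker sets must be pairwise disjoint")
  prev <- sum(vapply(states, `[[`, 0, "prevalence"))
  if (prev > 1 + 1e-8) stopf("state prevalences sum to %.3f > 1", prev)
  invisible(states)
}

#' Default planted states
#'
#' Four equally prevalent states, each over-expressing its own disjoint
#' marker programme — the synthetic analogue of the four shared cell states
#' discovered in residual triple-negative breast cancer.
#'
#' @param n_states number of states.
#' @param markers_per_state markers per state.
#' @param log2_effect in-state marker over-expression (log2 units).
#' @return list of [state_spec()] objects.
#' @export
default_states <- function(n_states = 4, markers_per_state = 150,
                           log2_effect = 2) {
  lapply(seq_len(n_states), function(k) {
    state_spec(
      state_id = paste0("S", k),
      marker_genes = sprintf("ST%dG%03d", k, seq_len(markers_per_state)),
      log2_effect = log2_effect,
      prevalence = 1 / n_states
    )
  })
}

# Builds the gene universe: planted markers, then the fixed special classes
# (mitochondrial, large-ribosomal, heat-shock, cell-cycle S / G2M), padded
# with housekeeping genes up to n_genes.
build_gene_universe <- function(states, n_genes = 2000) {
  cc <- cc_gene_sets()
  special <- data.frame(
    gene = c(sprintf("MT-G%02d", 1:20), sprintf("RPL%02d", 1:40),
             sprintf("HSPG%02d", 1:20), cc$s, cc$g2m),
    class = c(rep("mito", 20), rep("rpl", 40), rep("hsp", 20),
              rep("cc_s", length(cc$s)), rep("cc_g2m", length(cc$g2m))),
    stringsAsFactors = FALSE
  )
  mk <- do.call(rbind, lapply(states, function(s) {
    if (!length(s$marker_genes)) return(NULL)
    data.frame(gene = s$marker_genes,
               class = paste0("marker:", s$state_id),
               stringsAsFactors = FALSE)
  }))
  genes <- rbind(mk, special)
  if (anyDuplicated(genes$gene))
    stopf("marker gene names collide with reserved gene classes")
  n_hk <- n_genes - nrow(genes)
  if (n_hk < 0)
    stopf("n_genes = %d too small for %d markers + special classes",
          n_genes, if (is.null(mk)) 0L else nrow(mk))
  hk <- data.frame(gene = sprintf("HK%04d", seq_len(n_hk)),
                   class = "housekeeping", stringsAsFactors = FALSE)
  rbind(genes, hk)
}

#' Generate a multi-sample synthetic cohort with planted states
#'
#' Counts for gene g in cell c are negative binomial with mean
#' `L_c * w_gc / sum_g w_gc`, where the weight combines a log-normal gene
#' baseline, a per-sample per-gene log-normal batch factor, the state marker
#' effect, a cell-cycle programme for S/G2M cells and a per-cell
#' mitochondrial-content multiplier.  A small planted fraction of cells gets
#' extreme library sizes (low-quality truth flags).
#'
#' @param n_samples number of samples (>= 3; meta-clustering requires it).
#' @param states list of [state_spec()]; defaults to [default_states()].
#' @param cells_per_sample cells per sample.
#' @param batch_sd log-sd of the multiplicative per-sample per-gene batch
#'   factor.
#' @param seed integer RNG seed; output is bit-identical for a fixed seed.
#' @param n_genes gene-universe size.
#' @param theta negative-binomial size (dispersion = 1/theta).
#' @param lib_mean,lib_sd log-normal library-size parameters (mean counts,
#'   log-sd).
#' @param baseline_sdlog log-sd of gene baseline abundances.
#' @param phase_frac fraction of cells in S/G2M.
#' @param cc_effect log2 over-expression of cell-cycle genes in S/G2M cells.
#' @param lowq_frac planted fraction of low-quality cells (extreme UMI totals).
#' @param mito_target,mito_sd expected mitochondrial fraction and log-sd of
#'   its per-cell multiplier (gives a small tail above 5%).
#' @return an object of class `sa_cohort`: list with `samples` (named list of
#'   sparse genes x cells count matrices), `truth` (list with `cells` and
#'   `genes` data frames), and `params`.
#' @export
generate_cohort <- function(n_samples = 5, states = default_states(),
                            cells_per_sample = 2000, batch_sd = 0.2,
                            seed = 1, n_genes = 2000, theta = 10,
                            lib_mean = 4000, lib_sd = 0.3,
                            baseline_sdlog = 0.5,
                            phase_frac = 0.3, cc_effect = 2,
                            lowq_frac = 0.02,
                            mito_target = 0.025, mito_sd = 0.4) {
  if (n_samples < 3) stopf("n_samples must be >= 3 (shared-HVG rule needs 3)")
  if (cells_per_sample < 1) stopf("cells_per_sample must be positive")
  validate_states(states)
  genes <- build_gene_universe(states, n_genes)
  G <- nrow(genes)
  cc <- genes$class %in% c("cc_s", "cc_g2m")
  mito <- genes$class == "mito"
  state_ids <- vapply(states, `[[`, "", "state_id")
  prev <- vapply(states, `[[`, 0, "prevalence")
  # leftover prevalence mass becomes a baseline state with no programme
  leftover <- 1 - sum(prev)
  pool_ids <- c(state_ids, if (leftover > 1e-8) "S0")
  pool_p <- c(prev, if (leftover > 1e-8) leftover)

  with_seed(seed, {
    base <- exp(rnorm(G, 0, baseline_sdlog))
    # pin expected mitochondrial mass to mito_target of the transcriptome
    base[mito] <- base[mito] * (mito_target / (1 - mito_target)) *
      sum(base[!mito]) / sum(base[mito])

    samples <- vector("list", n_samples)
    names(samples) <- sprintf("SAMP%02d", seq_len(n_samples))
    cell_rows <- vector("list", n_samples)

    for (s in seq_len(n_samples)) {
      n <- cells_per_sample
      batch <- exp(rnorm(G, 0, batch_sd))
      w0 <- base * batch
      state <- sample(pool_ids, n, replace = TRUE, prob = pool_p)
      phase <- ifelse(runif(n) < phase_frac, "S/G2M", "G1")
      mito_mult <- exp(rnorm(n, 0, mito_sd))
      lib <- exp(rnorm(n, log(lib_mean), lib_sd))
      lowq <- runif(n) < lowq_frac
      lib[lowq] <- lib[lowq] * sample(c(0.03, 8), sum(lowq), replace = TRUE)

      W <- matrix(w0, nrow = G, ncol = n)
      for (k in seq_along(states)) {
        idx <- which(state == state_ids[k])
        if (!length(idx) || states[[k]]$log2_effect == 0) next
        mrows <- match(states[[k]]$marker_genes, genes$gene)
        W[mrows, idx] <- W[mrows, idx] * 2^states[[k]]$log2_effect
      }
      sg2m <- which(phase == "S/G2M")
      if (length(sg2m)) W[cc, sg2m] <- W[cc, sg2m] * 2^cc_effect
      W[mito, ] <- W[mito, , drop = FALSE] *
        rep(mito_mult, each = sum(mito))
      mu <- sweep(W, 2, lib / colSums(W), "*")
      counts <- matrix(rnbinom(G * n, mu = mu, size = theta), nrow = G)
      dimnames(counts) <- list(genes$gene,
                               sprintf("%s_C%05d", names(samples)[s], seq_len(n)))
      samples[[s]] <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                  "CsparseMatrix")
      cell_rows[[s]] <- data.frame(
        barcode = colnames(counts), sample_id = names(samples)[s],
        state_id = state, phase = phase, species = "human",
        is_low_quality = lowq, mito_mult = mito_mult,
        stringsAsFactors = FALSE
      )
    }
    structure(list(samples = samples,
                   truth = list(cells = do.call(rbind, cell_rows),
                                genes = genes),
                   params = list(n_samples = n_samples, states = states,
                                 cells_per_sample = cells_per_sample,
                                 batch_sd = batch_sd, seed = seed,
                                 theta = theta, lib_mean = lib_mean,
                                 phase_frac = phase_frac,
                                 cc_effect = cc_effect,
                                 lowq_frac = lowq_frac)),
              class = "sa_cohort")
  })
}

#' Generate a barnyard (human/mouse mixture) UMI matrix
#'
#' Singlets draw at least ~98% of UMIs from their own species' features;
#' doublets are sums of one human and one mouse singlet's draws.  A synthetic
#' doublet score (cross-species balance) is emitted so the consensus doublet
#' rule is testable without external tools.
#'
#' @param n_human,n_mouse numbers of singlet nuclei per species (> 0).
#' @param doublet_rate fraction in `[0, 0.3]`; `round(rate * (n_human +
#'   n_mouse))` additional doublet cells are appended.
#' @param seed RNG seed.
#' @param n_genes_per_species features per species genome.
#' @param contamination cross-species UMI fraction for singlets.
#' @param lib_mean,lib_sd,theta count-model parameters as in
#'   [generate_cohort()].
#' @return list with `counts` (sparse genes x cells, features prefixed
#'   `GRCh38_` / `mm10_`) and `truth` (per-cell data frame with species,
#'   doublet parents, species UMI tallies and a synthetic doublet score).
#' @export
generate_barnyard <- function(n_human, n_mouse, doublet_rate, seed = 1,
                              n_genes_per_species = 300,
                              contamination = 0.02,
                              lib_mean = 3000, lib_sd = 0.3, theta = 10) {
  if (n_human <= 0 || n_mouse <= 0) stopf("n_human and n_mouse must be positive")
  assert_scalar_num(doublet_rate, "doublet_rate", 0, 0.3)
  Gs <- n_genes_per_species
  feats <- c(sprintf("GRCh38_G%04d", seq_len(Gs)), sprintf("mm10_G%04d", seq_len(Gs)))
  is_human_feat <- rep(c(TRUE, FALSE), each = Gs)

  with_seed(seed, {
    p_h <- exp(rnorm(Gs, 0, 1)); p_h <- p_h / sum(p_h)
    p_m <- exp(rnorm(Gs, 0, 1)); p_m <- p_m / sum(p_m)
    draw_cells <- function(n, own_human) {
      w <- if (own_human) c((1 - contamination) * p_h, contamination * p_m)
      else c(contamination * p_h, (1 - contamination) * p_m)
      lib <- exp(rnorm(n, log(lib_mean), lib_sd))
      mu <- outer(w / sum(w), lib)
      matrix(rnbinom(length(mu), mu = mu, size = theta), nrow = 2 * Gs)
    }
    hm <- draw_cells(n_human, TRUE)
    mm <- draw_cells(n_mouse, FALSE)
    colnames(hm) <- sprintf("HUM%05d", seq_len(n_human))
    colnames(mm) <- sprintf("MOU%05d", seq_len(n_mouse))
    singlets <- cbind(hm, mm)
    n_d <- round(doublet_rate * (n_human + n_mouse))
    if (n_d > 0) {
      ph <- sample(n_human, n_d, replace = TRUE)
      pm <- sample(n_mouse, n_d, replace = TRUE)
      dbl <- hm[, ph, drop = FALSE] + mm[, pm, drop = FALSE]
      colnames(dbl) <- sprintf("DBL%05d", seq_len(n_d))
      counts <- cbind(singlets, dbl)
      parent_h <- c(rep(NA_character_, n_human + n_mouse), colnames(hm)[ph])
      parent_m <- c(rep(NA_character_, n_human + n_mouse), colnames(mm)[pm])
    } else {
      counts <- singlets
      parent_h <- parent_m <- rep(NA_character_, ncol(counts))
    }
    rownames(counts) <- feats
    h_umi <- colSums(counts[is_human_feat, , drop = FALSE])
    m_umi <- colSums(counts[!is_human_feat, , drop = FALSE])
    species <- c(rep("human", n_human), rep("mouse", n_mouse),
                 rep("doublet", max(n_d, 0)))
    truth <- data.frame(
      barcode = colnames(counts), species = species,
      parent_human = parent_h, parent_mouse = parent_m,
      human_umi = h_umi, mouse_umi = m_umi,
      # balance-based synthetic doublet score: 1 at 50/50 species mix
      doublet_score = 1 - abs(h_umi - m_umi) / pmax(h_umi + m_umi, 1),
      stringsAsFactors = FALSE
    )
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         truth = truth)
  })
}

#' Generate a bulk clinical cohort with a planted signature association
#'
#' @param n_patients number of patients (>= 20).
#' @param signature character vector of signature genes (non-empty).
#' @param effect for `outcome = "response"`, the expression shift (in SD
#'   units) added to signature genes in residual-disease (RD) patients; for
#'   `outcome = "survival"`, the log hazard ratio of the above-median
#'   signature-score group (0 = null).
#' @param outcome `"response"` (RD/pCR labels) or `"survival"`
#'   (time, event).
#' @param seed RNG seed.
#' @param n_background number of unassociated background genes.
#' @param rd_frac fraction of RD patients for response cohorts.
#' @param base_rate baseline exponential hazard (events per year).
#' @param max_follow_up administrative censoring time (years).
#' @return list with `expr` (genes x patients), plus `label` (factor RD/pCR)
#'   or `time`/`event`, and `truth` (planted effect and group).
#' @export
generate_clinical <- function(n_patients, signature, effect,
                              outcome = c("response", "survival"), seed = 1,
                              n_background = 200, rd_frac = 0.5,
                              base_rate = 0.12, max_follow_up = 15) {
  outcome <- match.arg(outcome)
  if (!length(signature)) stopf("`signature` must be non-empty")
  if (n_patients < 20) stopf("n_patients must be >= 20")
  genes <- c(unique(signature), sprintf("BG%04d", seq_len(n_background)))
  with_seed(seed, {
    expr <- matrix(rnorm(length(genes) * n_patients), nrow = length(genes),
                   dimnames = list(genes, sprintf("PT%04d", seq_len(n_patients))))
    sig_rows <- match(unique(signature), genes)
    if (outcome == "response") {
      label <- factor(ifelse(runif(n_patients) < rd_frac, "RD", "pCR"),
                      levels = c("RD", "pCR"))
      expr[sig_rows, label == "RD"] <- expr[sig_rows, label == "RD"] + effect
      list(expr = expr, label = label,
           truth = list(effect = effect, outcome = outcome))
    } else {
      score <- colMeans(expr[sig_rows, , drop = FALSE])
      high <- score > median(score)
      rate <- base_rate * exp(effect * as.numeric(high))
      t_event <- rexp(n_patients, rate)
      t_cens <- pmin(runif(n_patients, 2, 2 * max_follow_up), max_follow_up)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
      list(expr = expr, time = time, event = event,
           truth = list(effect = effect, outcome = outcome, high = high,
                        score = score))
    }
  })
}

#' Write a cohort as 10x-style MTX triplets plus truth tables
#'
#' One directory per sample with `matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`; truth tables as TSV at the top level.
#'
#' @param cohort an `sa_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sa_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(cohort$samples)) {
    sd <- file.path(dir, s)
    dir.create(sd, showWarnings = FALSE)
    m <- cohort$samples[[s]]
    Matrix::writeMM(m, file.path(sd, "matrix.mtx"))
    writeLines(colnames(m), file.path(sd, "barcodes.tsv"))
    writeLines(rownames(m), file.path(sd, "features.tsv"))
  }
  write.table(cohort$truth$cells, file.path(dir, "truth_cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth$genes, file.path(dir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style MTX triplet directory
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return sparse genes x cells count matrix.
#' @export
read_mtx_dir <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}
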