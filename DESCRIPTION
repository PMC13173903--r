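Package: stateatlas
Title: Multi-Sample Single-Nucleus RNA-Seq Meta-Clustering of Tumour Cell States
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@stateatlas.dev",
           role = c("aut", "cre"))
Description: Discovers transcriptionally distinct cell states shared across
    patient-derived xenograft samples profiled by single-nucleus RNA-seq.
    Provides barnyard (human/mouse) species assignment, density-based quality
    control with a dual-method doublet consensus rule, covariate-regressed
    negative-binomial normalisation, cell-cycle phase assignment, per-sample
    clustering with Davies-Bouldin resolution selection, cross-sample
    meta-clustering of cluster profiles, Fisher combined-probability marker
    aggregation, gene-set and regulon activity scoring, clinical response and
    survival association testing, and variant/copy-number filtering rules.
    A synthetic-data module generates every pipeline input with planted ground
    truth so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    igraph,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
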