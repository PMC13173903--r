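# Variant-retention filters and standardised copy-number calls for annotated
# whole-exome tables (annotation itself is upstream and out of scope).

#' Apply the four variant-retention filters
#'
#' A variant is retained iff all of:
#' 1. splice-site, or an exonic effect with a known functional consequence
#'    (configurable allow-list), excluding synonymous SNVs;
#' 2. read depth >= 5;
#' 3. HIGH or MODERATE predicted impact;
#' 4. absent from gnomAD, or population allele frequency < 0.001, or carrying
#'    any ClinVar annotation.
#'
#' @param variants data frame with columns `gene`, `effect`, `read_depth`,
#'   `impact`, `gnomad_af` (NA = absent), `clinvar` (NA/"" = absent).
#' @param allowed_effects exonic effect classes with known consequences.
#' @param splice_effects effect classes counted as splice-site.
#' @param min_depth,max_af thresholds (defaults 5 and 0.001).
#' @return the retained subset of `variants`.
#' @export
filter_variants <- function(variants,
                            allowed_effects = c("frameshift", "stopgain",
                                                "stoploss", "missense",
                                                "inframe_indel",
                                                "start_lost"),
                            splice_effects = c("splice", "splice_site",
                                               "splice_acceptor",
                                               "splice_donor"),
                            min_depth = 5, max_af = 0.001) {
  need <- c("gene", "effect", "read_depth", "impact", "gnomad_af", "clinvar")
  missing <- setdiff(need, names(variants))
  if (length(missing))
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  eff <- tolower(variants$effect)
  consequence_ok <- (eff %in% tolower(splice_effects) |
                       eff %in% tolower(allowed_effects)) &
    !grepl("synonymous", eff)
  depth_ok <- variants$read_depth >= min_depth
  impact_ok <- variants$impact %in% c("HIGH", "MODERATE")
  clinvar_ok <- !is.na(variants$clinvar) & nzchar(as.character(variants$clinvar))
  af_ok <- is.na(variants$gnomad_af) | variants$gnomad_af < max_af | clinvar_ok
  variants[consequence_ok & depth_ok & impact_ok & af_ok, , drop = FALSE]
}

#' Standardise copy-number segment log2 ratios and call gains/losses
#'
#' Within each sample, log2 fold changes are divided by the sample-specific
#' standard deviation (denominator n - 1); standardised values > 3 are
#' gains, < -3 losses, else neutral.  A zero SD makes every segment neutral
#' (warning).
#'
#' @param segments data frame with columns `sample` and `log2fc` (plus any
#'   positional columns, passed through).
#' @param threshold call threshold on the standardised scale (default 3).
#' @return `segments` with added `standardized` and `call` columns.
#' @export
standardize_cna <- function(segments, threshold = 3) {
  if (!all(c("sample", "log2fc") %in% names(segments)))
    stopf("missing required column(s): %s",
          paste(setdiff(c("sample", "log2fc"), names(segments)), collapse = ", "))
  out <- lapply(split(segments, segments$sample), function(d) {
    if (nrow(d) < 2) stopf("sample %s has < 2 segments", d$sample[1])
    s <- sd(d$log2fc)
    if (is.na(s) || s == 0) {
      warnf("sample %s: zero SD; all segments neutral", d$sample[1])
      d$standardized <- 0
    } else d$standardized <- d$log2fc / s
    d$call <- ifelse(d$standardized > threshold, "gain",
                     ifelse(d$standardized < -threshold, "loss", "neutral"))
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
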