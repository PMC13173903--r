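# Clinical validation: median-split prognosis grouping, proportional-hazards
# survival association, one-sided response tests per arm and the
# sample-size-weighted sum-of-z combination.

#' Split patients at the median score
#'
#' `"low"` iff score <= the 50% quantile (linear-interpolation), `"high"`
#' otherwise.
#'
#' @param scores per-patient numeric scores (n >= 4).
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 4) stopf("median_split needs n >= 4")
  med <- unname(quantile(scores, 0.5, type = 7))
  if (diff(range(scores)) == 0) warnf("all scores equal; everyone is 'low'")
  factor(ifelse(scores <= med, "low", "high"), levels = c("low", "high"))
}

#' Survival association of a score grouping within a follow-up horizon
#'
#' Censors all follow-up at `horizon` years, then fits a Cox proportional
#' hazards model of `high` versus `low` (delegated to
#' [survival::coxph()]).  Alternatively pass `continuous` scores to model
#' the score directly.
#'
#' @param groups factor from [median_split()] (ignored when `continuous`
#'   given).
#' @param time,event follow-up times (> 0) and event indicators (0/1).
#' @param horizon follow-up horizon in the time unit (default 10).
#' @param continuous optional numeric score to use instead of the grouping.
#' @return list with `hr`, `ci` (95%), `p` (Wald), `n_events`, `fit`.
#' @export
survival_assoc <- function(groups, time, event, horizon = 10,
                           continuous = NULL) {
  if (any(time <= 0)) stopf("times must be > 0")
  event <- as.integer(event)
  event[time > horizon] <- 0L
  time <- pmin(time, horizon)
  if (sum(event) == 0) {
    warnf("no events within the horizon; association undefined")
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                n_events = 0L, fit = NULL))
  }
  x <- if (is.null(continuous)) {
    g <- factor(groups, levels = c("low", "high"))
    if (any(table(g) == 0)) stopf("both groups must be non-empty")
    as.numeric(g == "high")
  } else continuous
  fit <- survival::coxph(survival::Surv(time, event) ~ x)
  s <- summary(fit)
  list(hr = unname(exp(coef(fit))), ci = unname(exp(confint(fit)))[1, ],
       p = unname(s$coefficients[1, "Pr(>|z|)"]), n_events = sum(event),
       fit = fit)
}

#' One-sided Wilcoxon response association within an arm
#'
#' Tests whether signature scores are shifted toward residual disease
#' (`direction = "RD-high"`) or toward complete response (`"pCR-high"`).
#' Exact test when both groups have fewer than 50 patients and no ties,
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param scores per-patient scores.
#' @param labels per-patient labels with values `"RD"` and `"pCR"`.
#' @param direction `"RD-high"` (default) or `"pCR-high"`.
#' @return one-sided p-value.
#' @export
response_assoc <- function(scores, labels, direction = c("RD-high", "pCR-high")) {
  direction <- match.arg(direction)
  rd <- scores[labels == "RD"]; pcr <- scores[labels == "pCR"]
  if (!length(rd) || !length(pcr))
    stopf("arm lacks one of the response classes; excluded")
  exact <- length(rd) < 50 && length(pcr) < 50
  suppressWarnings(
    if (direction == "RD-high")
      wilcox.test(rd, pcr, alternative = "greater", exact = exact,
                  correct = TRUE)$p.value
    else
      wilcox.test(pcr, rd, alternative = "greater", exact = exact,
                  correct = TRUE)$p.value
  )
}

#' Combine one-sided p-values by the weighted sum-of-z method
#'
#' `z_i = qnorm(1 - p_i)`, `Z = sum(w_i z_i) / sqrt(sum(w_i^2))`, combined
#' `p = 1 - pnorm(Z)`.  Weights are typically per-arm sample sizes.  P-values
#' at 0 or 1 are clamped with a warning.
#'
#' @param p per-arm one-sided p-values in `(0, 1)`.
#' @param weights positive per-arm weights (default equal: unweighted
#'   Stouffer).
#' @return combined one-sided p-value.
#' @export
combine_weighted_z <- function(p, weights = rep(1, length(p))) {
  if (length(p) != length(weights)) stopf("p and weights must align")
  if (any(weights <= 0)) stopf("weights must be > 0")
  eps <- .Machine$double.eps
  if (any(p <= 0 | p >= 1)) {
    warnf("p-values clamped into (0, 1)")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  z <- qnorm(1 - p)
  Z <- sum(weights * z) / sqrt(sum(weights^2))
  pnorm(Z, lower.tail = FALSE)
}
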