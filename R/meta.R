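# Cross-cohort combination: sample-size weighted z meta-analysis for
# directional markers, inverse-variance (standard-error approach) odds
# ratios, and Fisher's method for omnibus p-values. Cohorts are disjoint
# samples, so cross-cohort independence is assumed throughout.

#' Effective sample size of a case/control cohort
#'
#' \code{4 / (1/n_cases + 1/n_controls)}, the usual weighting convention of
#' sample-size based meta-analysis of case/control studies.
#' @param n_cases,n_controls Counts.
#' @export
effective_n <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}

#' Sample-size weighted meta-analysis
#'
#' Converts each cohort's p-value to a signed z (probit of p/2, sign from
#' the effect direction) and combines with weights proportional to the
#' square root of the effective sample size:
#' \code{z = sum(w_i z_i) / sqrt(sum(w_i^2))}.
#'
#' @param p Per-cohort two-sided p-values.
#' @param direction Per-cohort effect signs (+1/-1, or any signed number).
#' @param n_eff Per-cohort effective sample sizes.
#' @return list(z, p, method).
#' @export
meta_samplesize <- function(p, direction, n_eff) {
  stopifnot(length(p) == length(direction), length(p) == length(n_eff))
  if (any(is.na(direction))) stop("missing effect direction")
  z <- sign(direction) * stats::qnorm(p / 2, lower.tail = FALSE)
  w <- sqrt(n_eff)
  zc <- sum(w * z) / sqrt(sum(w^2))
  list(z = zc, p = 2 * stats::pnorm(-abs(zc)), method = "samplesize")
}

#' Inverse-variance (standard error approach) meta-analysis
#'
#' Combines per-cohort log odds ratios with inverse-variance weights and
#' reports the combined odds ratio with its 95\% confidence interval.
#'
#' @param beta Per-cohort log odds ratios.
#' @param se Per-cohort standard errors (> 0).
#' @return list(beta, se, or, lci, uci, z, p, method).
#' @export
meta_se <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  if (any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  z <- b / s
  list(beta = b, se = s, or = exp(b),
       lci = exp(b - 1.959964 * s), uci = exp(b + 1.959964 * s),
       z = z, p = 2 * stats::pnorm(-abs(z)), method = "se")
}

#' Fisher's method for combining p-values
#'
#' \code{X = -2 sum(log p_i)} referred to a chi-square with 2k degrees of
#' freedom; used for omnibus p-values, where effect directions are not
#' available. Zero p-values are clamped to the smallest positive
#' representable double (with a warning).
#'
#' @param p Vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
fisher_combine <- function(p) {
  stopifnot(length(p) >= 1, all(p <= 1), all(p >= 0))
  if (any(p == 0)) {
    warning("p-value of 0 clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}
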