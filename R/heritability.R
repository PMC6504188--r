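# Liability-scale heritability from risk-residue odds ratios, following
# the threshold (liability) model of So & Sham: genotype frequencies under
# Hardy-Weinberg, genotype relative risks multiplicative on the odds scale
# anchored to the disease prevalence, and per-genotype mean liability
# shifts recovered by inverting the normal threshold model.

#' Liability variance contributed by one risk residue
#'
#' Given a risk-allele frequency, a per-allele odds ratio and the disease
#' prevalence K, computes the proportion of liability variance explained:
#' genotype frequencies are Hardy-Weinberg; genotype penetrances follow
#' multiplicative odds anchored so the population risk equals K; each
#' genotype's mean liability is recovered from its penetrance under the
#' normal threshold model; Vg is the variance of those genotype means
#' (total liability variance 1).
#'
#' @param raf Risk allele frequency, in (0, 1).
#' @param or_value Per-allele odds ratio, > 0.
#' @param K Disease prevalence, in (0, 1).
#' @return Vg, the proportion of liability variance explained.
#' @export
vg_from_or <- function(raf, or_value, K) {
  if (raf <= 0 || raf >= 1) stop("raf must be inside (0,1)")
  if (or_value <= 0) stop("odds ratio must be positive")
  if (K <= 0 || K >= 1) stop("prevalence K must be inside (0,1)")
  pg <- c((1 - raf)^2, 2 * raf * (1 - raf), raf^2)   # 0,1,2 risk alleles
  # penetrances: odds multiplicative in allele count, anchored to K
  pen <- function(logodds0) stats::plogis(logodds0 + log(or_value) * 0:2)
  base <- stats::uniroot(function(lo) sum(pg * pen(lo)) - K,
                         c(-60, 60), tol = 1e-12)$root
  f <- pen(base)
  # threshold model: f_g = P(N(mu_g,1) > T) with T = qnorm(1-K)
  Tthr <- stats::qnorm(1 - K)
  mu <- Tthr - stats::qnorm(1 - f)
  mbar <- sum(pg * mu)
  sum(pg * (mu - mbar)^2)
}

#' Total percent heritability from a set of independent residues
#'
#' Sums per-residue Vg over the included residues after removing any
#' residue flagged as a proxy of another included one (the tight-linkage
#' exclusion: when two positions tag the same signal only one enters the
#' total), and reports the result as a percentage.
#'
#' @param residues data.frame with columns \code{raf}, \code{or} and
#'   optionally \code{name} and \code{proxy_of} (name of another included
#'   residue this one tags; such rows are dropped).
#' @param K Disease prevalence.
#' @return list(percent, table) where table has the per-residue Vg.
#' @export
total_heritability <- function(residues, K) {
  stopifnot(nrow(residues) >= 1, all(c("raf", "or") %in% names(residues)))
  if (!"name" %in% names(residues))
    residues$name <- paste0("residue", seq_len(nrow(residues)))
  keep <- rep(TRUE, nrow(residues))
  if ("proxy_of" %in% names(residues))
    keep <- is.na(residues$proxy_of) | !(residues$proxy_of %in% residues$name)
  tab <- residues[keep, , drop = FALSE]
  tab <- tab[!duplicated(tab$name), , drop = FALSE]
  tab$vg <- mapply(vg_from_or, tab$raf, tab$or, MoreArgs = list(K = K))
  list(percent = 100 * sum(tab$vg), table = tab)
}
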