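# Independent oracles and small fixture builders shared across tests.

# --- liability-model oracle -------------------------------------------------
# Recomputes Vg through numerical integration of the normal threshold model:
# the liability threshold and the per-genotype mean shifts are recovered by
# root-finding on integrate()d normal tails rather than closed-form quantile
# inversion.
oracle_vg <- function(raf, or_value, K) {
  pg <- c((1 - raf)^2, 2 * raf * (1 - raf), raf^2)
  pen <- function(lo) plogis(lo + log(or_value) * 0:2)
  base <- uniroot(function(lo) sum(pg * pen(lo)) - K, c(-60, 60),
                  tol = 1e-12)$root
  f <- pen(base)
  tail_above <- function(a) integrate(dnorm, a, Inf, rel.tol = 1e-12)$value
  Tthr <- uniroot(function(t) tail_above(t) - K, c(-10, 10), tol = 1e-12)$root
  mu <- vapply(f, function(fg)
    uniroot(function(m) tail_above(Tthr - m) - fg, c(-15, 15),
            tol = 1e-12)$root, numeric(1))
  mbar <- sum(pg * mu)
  sum(pg * (mu - mbar)^2)
}

# --- brute-force 2-locus haplotype ML ---------------------------------------
# Grid search over the 3-simplex of haplotype frequencies (coarse-to-fine,
# final step 1e-5) maximizing the phase-ambiguous multinomial likelihood of
# 2-locus biallelic genotype data. geno: matrix n x 2 of 0/1/2 counts of
# allele "1".
brute_force_hap_ml <- function(geno) {
  # 9 genotype classes
  cls <- as.vector(table(factor(geno[, 1], 0:2), factor(geno[, 2], 0:2)))
  loglik_vec <- function(h11, h10, h01) {
    h00 <- 1 - h11 - h10 - h01
    P <- cbind(h00^2, 2 * h00 * h10, h10^2,          # gB = 0 column-major
               2 * h00 * h01, 2 * (h11 * h00 + h10 * h01), 2 * h10 * h11,
               h01^2, 2 * h01 * h11, h11^2)
    logP <- matrix(0, nrow(P), ncol(P))
    pos <- P > 0
    logP[pos] <- log(P[pos])
    ll <- rowSums(sweep(logP, 2, cls, `*`))
    bad <- h00 < 0 | rowSums(P <= 0 & rep(cls, each = nrow(P)) > 0) > 0
    ll[bad] <- -Inf
    ll
  }
  grid_around <- function(center, step, span) {
    vals <- lapply(center, function(c0)
      seq(max(0, c0 - span), min(1, c0 + span), by = step))
    expand.grid(h11 = vals[[1]], h10 = vals[[2]], h01 = vals[[3]])
  }
  g <- grid_around(c(0.5, 0.5, 0.5), 0.025, 0.5)
  ll <- loglik_vec(g$h11, g$h10, g$h01)
  best <- as.numeric(g[which.max(ll), ])
  for (step in c(2e-3, 2e-4, 1e-5)) {
    g <- grid_around(best, step, step * 15)
    ll <- loglik_vec(g$h11, g$h10, g$h01)
    best <- as.numeric(g[which.max(ll), ])
  }
  c(h11 = best[1], h10 = best[2], h01 = best[3],
    h00 = 1 - sum(best))
}

# --- small simulation fixtures ----------------------------------------------

# Minimal one-gene configuration (DRB1 toy map only, no LD block).
one_gene_config <- function(seed, n_cases, n_controls, causal = NULL,
                            sex_beta = 0, pc_betas = c(0, 0, 0),
                            default_r2 = 1, subpheno = NULL) {
  map <- toy_allele_map()
  map <- map[map$gene == "DRB1", ]
  freqs <- list(DRB1 = c("09:01" = 0.15, "15:01" = 0.10, "04:01" = 0.06,
                         "04:05" = 0.07, "03:01" = 0.05, "08:03" = 0.07,
                         "01:03" = 0.02, "04:02" = 0.03, "07:01" = 0.08,
                         "11:01" = 0.12, "14:01" = 0.06, "14:04" = 0.04,
                         "12:01" = 0.10, "01:01" = 0.05))
  sim_config(seed = seed,
             cohorts = list(C1 = list(n_cases = n_cases,
                                      n_controls = n_controls,
                                      pc_offset = c(0, 0, 0))),
             allele_freqs = freqs, allele_map = map, causal_effects = causal,
             sex_beta = sex_beta, pc_betas = pc_betas,
             default_r2 = default_r2, subpheno = subpheno, snp_tags = FALSE)
}

# Two-gene configuration without complete cross-position proxies, used for
# planted-signal recovery experiments (DRB1 positions 13/26/37, B 9/63).
recovery_config <- function(seed, n_cases, n_controls,
                            beta_drb1_13R = log(1.4), beta_b_9D = log(1.3)) {
  map <- rbind(
    data.frame(gene = "DRB1", allele = "15:01",
               aa_pos = c(13, 26, 37), residue = c("R", "F", "S")),
    data.frame(gene = "DRB1", allele = "16:02",
               aa_pos = c(13, 26, 37), residue = c("R", "Y", "N")),
    data.frame(gene = "DRB1", allele = "09:01",
               aa_pos = c(13, 26, 37), residue = c("F", "F", "N")),
    data.frame(gene = "DRB1", allele = "11:01",
               aa_pos = c(13, 26, 37), residue = c("S", "F", "Y")),
    data.frame(gene = "DRB1", allele = "07:01",
               aa_pos = c(13, 26, 37), residue = c("Y", "L", "F")),
    data.frame(gene = "DRB1", allele = "03:01",
               aa_pos = c(13, 26, 37), residue = c("S", "Y", "N")),
    data.frame(gene = "B", allele = "58:01",
               aa_pos = c(9, 63), residue = c("D", "N")),
    data.frame(gene = "B", allele = "40:01",
               aa_pos = c(9, 63), residue = c("H", "E")),
    data.frame(gene = "B", allele = "15:11",
               aa_pos = c(9, 63), residue = c("Y", "N")),
    data.frame(gene = "B", allele = "46:01",
               aa_pos = c(9, 63), residue = c("Y", "E")))
  freqs <- list(
    DRB1 = c("15:01" = 0.12, "16:02" = 0.06, "09:01" = 0.20,
             "11:01" = 0.30, "07:01" = 0.20, "03:01" = 0.12),
    B = c("58:01" = 0.15, "40:01" = 0.35, "15:11" = 0.20, "46:01" = 0.30))
  causal <- data.frame(gene = c("DRB1", "B"), aa_pos = c(13, 9),
                       residue = c("R", "D"),
                       beta = c(beta_drb1_13R, beta_b_9D))
  causal <- causal[causal$beta != 0, , drop = FALSE]
  if (!nrow(causal)) causal <- NULL
  sim_config(seed = seed,
             cohorts = list(C1 = list(n_cases = n_cases,
                                      n_controls = n_controls,
                                      pc_offset = c(0, 0, 0))),
             allele_freqs = freqs, allele_map = map, causal_effects = causal,
             sex_beta = log(2), pc_betas = c(0.1, 0, 0), snp_tags = FALSE)
}

# One multi-residue amino-acid position drawn directly (multinomial
# chromosomes), with a covariate-free null panel; fast building block for
# calibration loops.
draw_position_cohort <- function(n, res_freqs, gene = "DRB1", aa_pos = 13) {
  res <- names(res_freqs)
  chrom <- sample(res, 2 * n, replace = TRUE, prob = res_freqs)
  counts <- vapply(res, function(r) {
    v <- as.integer(chrom == r)
    as.numeric(v[seq(1, 2 * n, 2)] + v[seq(2, 2 * n, 2)])
  }, numeric(n))
  ids <- vapply(res, function(r)
    sprintf("AA_%s_%d_%d_%s", gene, aa_pos, 32546547L + 3L * aa_pos, r), "")
  colnames(counts) <- ids
  rownames(counts) <- sprintf("I%05d", seq_len(n))
  dm <- hla_dosage(counts, rep(1, length(res)))
  panel <- as_panel(data.frame(
    individual_id = rownames(counts),
    status = rbinom(n, 1, 0.3), sex = rbinom(n, 1, 0.5),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), cohort = "C1"))
  list(dm = dm, panel = panel,
       position = group_positions(dm)[[1]])
}
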