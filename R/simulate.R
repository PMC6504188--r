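# Synthetic imputed-HLA cohort generator.
#
# The generator inverts the analysis model: chromosomes carry one classical
# allele per gene (drawn from marginal or joint haplotype frequency tables),
# residues follow deterministically from an allele->protein map, case status
# is Bernoulli under a logistic model on sex, PCs and planted residue
# dosages, and imputation is emulated as shrinkage-plus-Gaussian noise on
# the dosage scale.

GENE_BP <- c(A = 29910247L, C = 31236526L, B = 31321649L,
             DRB1 = 32546547L, DQA1 = 32605183L, DQB1 = 32627244L,
             DPA1 = 33032346L, DPB1 = 33043703L)

aa_marker_id <- function(gene, aa_pos, residue) {
  sprintf("AA_%s_%d_%d_%s", gene, aa_pos,
          GENE_BP[[gene]] + 3L * (aa_pos - 1L), residue)
}

allele_marker_id <- function(gene, code) {
  sprintf("HLA_%s_%s", gene, gsub(":", "", code, fixed = TRUE))
}

#' Simulation configuration
#'
#' Assembles and validates the configuration driving the synthetic cohort
#' generator. Effects are on the log-odds scale per dosage unit.
#'
#' @param seed Integer seed; a single stream keyed by this seed drives every
#'   stochastic step in a documented order (cohort by cohort: haplotypes,
#'   sex, PCs, status, sub-phenotypes, imputation noise).
#' @param cohorts Named list; each element a list with \code{n_cases},
#'   \code{n_controls} and optionally \code{pc_offset} (length-3) and
#'   \code{allele_freqs} overriding the shared tables.
#' @param allele_freqs Named list (gene -> named numeric of 4-digit allele
#'   frequencies summing to 1).
#' @param allele_map An \code{allele_protein_map} covering every allele.
#' @param haplo_ld Optional list of LD blocks, each a list with
#'   \code{genes} (character) and \code{haps} (data.frame with one column
#'   per gene plus \code{freq}); genes in a block are drawn jointly.
#' @param causal_effects data.frame(gene, aa_pos, residue, beta) of planted
#'   residue effects.
#' @param sex_beta,pc_betas,p_female Covariate model: sex effect on
#'   log-odds (default \code{log(9)}, which makes cases roughly 90\% female
#'   from a 50/50 population), PC effects, population female fraction.
#' @param default_r2,target_r2 Imputation quality: shared target r2 and
#'   optional named per-marker overrides.
#' @param subpheno Named list (antibody -> list(baseline, effects)) where
#'   \code{baseline} is the positive fraction among cases at zero effect and
#'   \code{effects} a data.frame(gene, aa_pos, residue, beta).
#' @param snp_tags Add tag-SNP markers per gene (and an rs-style tag of the
#'   most frequent DRB1 allele) to exercise the SNP marker path.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed, cohorts, allele_freqs, allele_map,
                       haplo_ld = NULL, causal_effects = NULL,
                       sex_beta = log(9), pc_betas = c(0.1, 0, 0),
                       p_female = 0.5, default_r2 = 1, target_r2 = NULL,
                       subpheno = NULL, snp_tags = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.list(cohorts), length(cohorts) >= 1L, !is.null(names(cohorts)))
  allele_map <- as_allele_map(allele_map)
  for (g in names(allele_freqs)) {
    f <- allele_freqs[[g]]
    if (abs(sum(f) - 1) > 1e-9)
      stop("allele frequencies for gene ", g, " sum to ", sum(f), ", not 1")
    if (any(f < 0)) stop("negative allele frequency for gene ", g)
    missing_alleles <- setdiff(names(f)[f > 0],
                               allele_map$allele[allele_map$gene == g])
    if (length(missing_alleles))
      stop("alleles absent from allele map for ", g, ": ",
           paste(missing_alleles, collapse = ", "))
  }
  if (!is.null(haplo_ld)) {
    for (blk in haplo_ld) {
      stopifnot(all(blk$genes %in% names(allele_freqs)),
                all(c(blk$genes, "freq") %in% names(blk$haps)))
      if (abs(sum(blk$haps$freq) - 1) > 1e-9)
        stop("haplotype block frequencies do not sum to 1")
    }
  }
  if (!is.null(causal_effects))
    stopifnot(all(c("gene", "aa_pos", "residue", "beta") %in% names(causal_effects)))
  if (!is.null(target_r2))
    stopifnot(all(target_r2 > 0), all(target_r2 <= 1))
  stopifnot(default_r2 > 0, default_r2 <= 1)
  structure(list(seed = as.integer(seed), cohorts = cohorts,
                 allele_freqs = allele_freqs, allele_map = allele_map,
                 haplo_ld = haplo_ld, causal_effects = causal_effects,
                 sex_beta = sex_beta, pc_betas = pc_betas,
                 p_female = p_female, default_r2 = default_r2,
                 target_r2 = target_r2, subpheno = subpheno,
                 snp_tags = snp_tags),
            class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path Path to a YAML (.yml/.yaml) or JSON file mirroring the
#'   arguments of \code{\link{sim_config}}; \code{allele_map},
#'   \code{causal_effects} and sub-phenotype \code{effects} are given as
#'   lists of records.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  to_df <- function(x) {
    df <- if (is.data.frame(x)) x else do.call(rbind.data.frame, x)
    for (cc in intersect(c("aa_pos", "beta"), names(df)))
      df[[cc]] <- as.numeric(df[[cc]])
    df
  }
  raw$allele_map <- to_df(raw$allele_map)
  if (!is.null(raw$causal_effects)) raw$causal_effects <- to_df(raw$causal_effects)
  if (!is.null(raw$subpheno))
    raw$subpheno <- lapply(raw$subpheno, function(sp) {
      if (!is.null(sp$effects)) sp$effects <- to_df(sp$effects)
      sp
    })
  if (!is.null(raw$haplo_ld))
    raw$haplo_ld <- lapply(raw$haplo_ld, function(b) {
      b$haps <- to_df(b$haps); b
    })
  if (!is.null(raw$allele_freqs))
    raw$allele_freqs <- lapply(raw$allele_freqs, unlist)
  do.call(sim_config, raw)
}

#' Draw phased classical-allele haplotypes
#'
#' One 4-digit allele per gene per chromosome, drawn from the configured
#' joint haplotype tables for genes inside an LD block and from marginal
#' frequency tables elsewhere.
#'
#' @param cfg A \code{sim_config}.
#' @param n_chromosomes Number of chromosomes to draw.
#' @param cohort Optional cohort label (uses its frequency overrides).
#' @return Character matrix, chromosomes x genes, of 4-digit allele codes.
#' @export
simulate_haplotypes <- function(cfg, n_chromosomes, cohort = NULL) {
  freqs <- cfg$allele_freqs
  if (!is.null(cohort) && !is.null(cfg$cohorts[[cohort]]$allele_freqs)) {
    ov <- cfg$cohorts[[cohort]]$allele_freqs
    freqs[names(ov)] <- ov
  }
  genes <- names(freqs)
  out <- matrix(NA_character_, n_chromosomes, length(genes),
                dimnames = list(NULL, genes))
  done <- character(0)
  for (blk in cfg$haplo_ld) {
    h <- blk$haps
    idx <- sample.int(nrow(h), n_chromosomes, replace = TRUE, prob = h$freq)
    for (g in blk$genes) out[, g] <- h[[g]][idx]
    done <- c(done, blk$genes)
  }
  for (g in setdiff(genes, done)) {
    f <- freqs[[g]]
    out[, g] <- sample(names(f), n_chromosomes, replace = TRUE, prob = f)
  }
  out
}

#' Build a two-gene joint haplotype table with target allele correlation
#'
#' Couples one allele of each gene at a chosen squared correlation while
#' preserving both marginal frequency tables; all other combinations stay
#' proportional to the product of their marginals.
#'
#' @param fA,fB Named marginal frequency vectors for the two genes.
#' @param aA,aB The coupled allele of each gene.
#' @param r2 Target squared correlation between the two allele indicators.
#' @return data.frame with columns named after the two vectors' genes must
#'   be assigned by the caller; here \code{a1}, \code{a2}, \code{freq}.
#' @export
couple_alleles <- function(fA, fB, aA, aB, r2) {
  pa <- fA[[aA]]; pb <- fB[[aB]]
  D <- sqrt(r2 * pa * (1 - pa) * pb * (1 - pb))
  fab <- pa * pb + D
  if (fab > min(pa, pb) + 1e-12)
    stop("target r2 unattainable for these frequencies")
  fab <- min(fab, min(pa, pb))
  grid <- expand.grid(a1 = names(fA), a2 = names(fB),
                      stringsAsFactors = FALSE)
  freq <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a1[i]; b <- grid$a2[i]
    freq[i] <-
      if (a == aA && b == aB) fab
      else if (a == aA) (pa - fab) * fB[[b]] / (1 - pb)
      else if (b == aB) (pb - fab) * fA[[a]] / (1 - pa)
      else (1 - pa - pb + fab) * fA[[a]] * fB[[b]] / ((1 - pa) * (1 - pb))
  }
  data.frame(grid, freq = freq)
}

# True dosage matrix (alleles, 2-digit groups, residues, tag SNPs) from
# phased haplotypes; residues derive deterministically from the allele map.
build_true_dosage <- function(cfg, haps) {
  n <- nrow(haps) / 2L
  ind <- sprintf("I%05d", seq_len(n))
  genes <- colnames(haps)
  cols <- list(); r2 <- c()
  map <- cfg$allele_map
  for (g in genes) {
    codes <- sort(unique(map$allele[map$gene == g]))
    codes <- codes[codes %in% unique(haps[, g]) |
                   codes %in% names(cfg$allele_freqs[[g]])]
    counts <- vapply(codes, function(cd) {
      v <- as.integer(haps[, g] == cd)
      as.numeric(v[seq(1, 2 * n, 2)] + v[seq(2, 2 * n, 2)])
    }, numeric(n))
    colnames(counts) <- allele_marker_id(g, codes)
    cols[[length(cols) + 1L]] <- counts
    # 2-digit allele groups
    grp <- substr(codes, 1, 2)
    for (gg in unique(grp)) {
      gcount <- rowSums(counts[, grp == gg, drop = FALSE])
      cols[[length(cols) + 1L]] <-
        matrix(gcount, ncol = 1,
               dimnames = list(NULL, sprintf("HLA_%s_%s", g, gg)))
    }
    # residues
    mg <- map[map$gene == g & map$allele %in% codes, ]
    for (p in sort(unique(mg$aa_pos))) {
      mp <- mg[mg$aa_pos == p, ]
      for (res in sort(unique(mp$residue))) {
        carrying <- allele_marker_id(g, mp$allele[mp$residue == res])
        dos <- rowSums(counts[, intersect(carrying, colnames(counts)),
                              drop = FALSE])
        cols[[length(cols) + 1L]] <-
          matrix(dos, ncol = 1, dimnames = list(NULL, aa_marker_id(g, p, res)))
      }
    }
    if (isTRUE(cfg$snp_tags)) {
      top <- names(which.max(cfg$allele_freqs[[g]]))
      v <- as.integer(haps[, g] == top)
      flip <- stats::runif(2 * n) < 0.02
      v <- ifelse(flip, 1L - v, v)
      snp <- v[seq(1, 2 * n, 2)] + v[seq(2, 2 * n, 2)]
      id <- if (g == "DRB1") "rs9271348" else
        sprintf("SNP_%s_%d", g, GENE_BP[[g]] - 1000L)
      cols[[length(cols) + 1L]] <-
        matrix(snp, ncol = 1, dimnames = list(NULL, id))
    }
  }
  d <- do.call(cbind, cols)
  rownames(d) <- ind
  storage.mode(d) <- "double"
  hla_dosage(d, rep(1, ncol(d)))
}

#' Draw case/control status under the planted logistic model
#'
#' Solves the intercept numerically so the expected case fraction matches
#' the requested one, then draws Bernoulli status.
#'
#' @param dm True-dosage \code{hla_dosage}.
#' @param covars data.frame with \code{sex}, \code{pc1..pc3}.
#' @param cfg A \code{sim_config}.
#' @param case_fraction Target expected case fraction.
#' @return list(status, theta).
#' @export
assign_status <- function(dm, covars, cfg, case_fraction) {
  stopifnot(case_fraction > 0, case_fraction < 1)
  lp <- cfg$sex_beta * covars$sex +
    as.matrix(covars[, c("pc1", "pc2", "pc3")]) %*% cfg$pc_betas
  lp <- as.numeric(lp)
  if (!is.null(cfg$causal_effects) && nrow(cfg$causal_effects)) {
    ce <- cfg$causal_effects
    for (i in seq_len(nrow(ce))) {
      id <- aa_marker_id(ce$gene[i], ce$aa_pos[i], ce$residue[i])
      if (!id %in% colnames(dm$dosage))
        stop("causal marker not present in cohort: ", id)
      lp <- lp + ce$beta[i] * dm$dosage[, id]
    }
  }
  theta <- stats::uniroot(function(th) mean(stats::plogis(th + lp)) - case_fraction,
                          c(-40, 40), tol = 1e-10)$root
  status <- as.integer(stats::runif(length(lp)) < stats::plogis(theta + lp))
  list(status = status, theta = theta)
}

#' Emulate imputation noise on dosages
#'
#' Per marker, the noisy dosage is a shrinkage-plus-Gaussian perturbation of
#' the true dosage clipped to [0, 2], tuned so the squared correlation with
#' the truth is approximately the target r2; the marker's recorded
#' imputation quality is set to the realized squared correlation.
#'
#' @param dm True-dosage \code{hla_dosage}.
#' @param target_r2 Named per-marker targets (overrides), in (0, 1].
#' @param default_r2 Target for markers not named in \code{target_r2}.
#' @return Noisy \code{hla_dosage}.
#' @export
add_imputation_noise <- function(dm, target_r2 = NULL, default_r2 = 1) {
  d <- dm$dosage
  r2 <- rep(default_r2, ncol(d))
  names(r2) <- colnames(d)
  if (!is.null(target_r2)) {
    ov <- intersect(names(target_r2), colnames(d))
    r2[ov] <- target_r2[ov]
  }
  realized <- rep(1, ncol(d))
  for (j in seq_len(ncol(d))) {
    if (r2[j] >= 1) next
    x <- d[, j]
    v <- stats::var(x)
    if (v < 1e-12) next
    mu <- mean(x)
    z <- stats::rnorm(length(x))
    sig0 <- sqrt(r2[j] * (1 - r2[j]) * v)
    make <- function(k) pmin(2, pmax(0, mu + r2[j] * (x - mu) + k * sig0 * z))
    rlz <- function(k) {
      r <- suppressWarnings(stats::cor(x, make(k)))^2
      if (is.na(r)) 0 else r
    }
    # clipping to [0,2] raises the realized correlation above the nominal
    # value, so calibrate the noise scale by bisection against the target
    k <- 1
    if (abs(rlz(1) - r2[j]) > 0.002) {
      lo <- 0; hi <- 1
      while (rlz(hi) > r2[j] && hi < 64) hi <- hi * 2
      for (it in 1:18) {
        mid <- (lo + hi) / 2
        if (rlz(mid) > r2[j]) lo <- mid else hi <- mid
      }
      k <- (lo + hi) / 2
    }
    y <- make(k)
    d[, j] <- y
    realized[j] <- suppressWarnings(stats::cor(x, y))^2
    if (is.na(realized[j])) realized[j] <- 0
  }
  hla_dosage(d, realized)
}

#' Draw autoantibody sub-phenotypes among cases
#'
#' Antibody status is drawn per case from a logistic model on the configured
#' residue markers; controls are set missing.
#'
#' @param panel An \code{hla_panel} with status filled in.
#' @param dm True-dosage \code{hla_dosage} (same individuals).
#' @param cfg A \code{sim_config} with a \code{subpheno} block.
#' @return The panel with antibody columns appended.
#' @export
assign_subphenotypes <- function(panel, dm, cfg) {
  if (is.null(cfg$subpheno)) return(panel)
  for (ab in names(cfg$subpheno)) {
    sp <- cfg$subpheno[[ab]]
    lp <- rep(stats::qlogis(sp$baseline), nrow(panel))
    if (!is.null(sp$effects) && nrow(sp$effects)) {
      for (i in seq_len(nrow(sp$effects))) {
        id <- aa_marker_id(sp$effects$gene[i], sp$effects$aa_pos[i],
                           sp$effects$residue[i])
        lp <- lp + sp$effects$beta[i] * dm$dosage[, id]
      }
    }
    val <- as.integer(stats::runif(nrow(panel)) < stats::plogis(lp))
    val[panel$status != 1L] <- NA_integer_
    panel[[ab]] <- val
  }
  panel
}

#' Simulate a full multi-cohort imputed-HLA study
#'
#' Runs the whole generative chain cohort by cohort: haplotypes, covariates,
#' status, sub-phenotypes, then imputation noise. Identical seeds give
#' bit-identical cohorts.
#'
#' @param cfg A \code{sim_config}.
#' @return list with \code{dosage} (noisy \code{hla_dosage}),
#'   \code{dosage_true}, \code{panel} (\code{hla_panel}),
#'   \code{haplotypes} (per-cohort character matrices) and \code{theta}
#'   (per-cohort solved intercepts).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  panels <- list(); dtrue <- list(); haps_all <- list(); thetas <- c()
  offset_default <- 0
  for (ci in seq_along(cfg$cohorts)) {
    lab <- names(cfg$cohorts)[ci]
    co <- cfg$cohorts[[ci]]
    n <- co$n_cases + co$n_controls
    haps <- simulate_haplotypes(cfg, 2L * n, cohort = lab)
    dm <- build_true_dosage(cfg, haps)
    rownames(dm$dosage) <- sprintf("%s_%05d", lab, seq_len(n))
    dm$individuals <- rownames(dm$dosage)
    off <- if (!is.null(co$pc_offset)) co$pc_offset else c(0.4 * (ci - 1), 0, 0)
    covars <- data.frame(
      sex = as.integer(stats::runif(n) < cfg$p_female),
      pc1 = stats::rnorm(n) + off[1],
      pc2 = stats::rnorm(n) + off[2],
      pc3 = stats::rnorm(n) + off[3])
    st <- assign_status(dm, covars, cfg, co$n_cases / n)
    panel <- data.frame(individual_id = rownames(dm$dosage),
                        status = st$status, sex = covars$sex,
                        pc1 = covars$pc1, pc2 = covars$pc2, pc3 = covars$pc3,
                        cohort = lab, stringsAsFactors = FALSE)
    panel <- assign_subphenotypes(panel, dm, cfg)
    panels[[lab]] <- panel
    dtrue[[lab]] <- dm
    haps_all[[lab]] <- haps
    thetas[lab] <- st$theta
  }
  panel <- do.call(rbind, panels)
  rownames(panel) <- NULL
  # antibody columns may differ if subpheno absent; rbind is fine since all
  # cohorts share the same config
  dosage_true <- hla_dosage(do.call(rbind, lapply(dtrue, `[[`, "dosage")),
                            rep(1, ncol(dtrue[[1]]$dosage)))
  noisy <- add_imputation_noise(dosage_true, cfg$target_r2, cfg$default_r2)
  list(dosage = noisy, dosage_true = dosage_true, panel = as_panel(panel),
       haplotypes = haps_all, theta = thetas)
}
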