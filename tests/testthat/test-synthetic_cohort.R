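test_that("identical seeds give bit-identical cohorts", {
  s1 <- simulate_cohort(toy_asia_config(seed = 42, scale = 0.05))
  s2 <- simulate_cohort(toy_asia_config(seed = 42, scale = 0.05))
  expect_identical(s1$dosage$dosage, s2$dosage$dosage)
  expect_identical(s1$panel, s2$panel)
  s3 <- simulate_cohort(toy_asia_config(seed = 43, scale = 0.05))
  expect_false(identical(s1$dosage$dosage, s3$dosage$dosage))
})

test_that("haplotype draws match configured frequencies and LD", {
  cfg <- toy_asia_config(seed = 5)
  set.seed(99)
  haps <- simulate_haplotypes(cfg, 1e5)
  # binomial bound on a marginal frequency
  f <- mean(haps[, "DRB1"] == "15:01")
  se <- sqrt(0.10 * 0.90 / 1e5)
  expect_lt(abs(f - 0.10), 3 * se)
  # degenerate case: single allele
  cfg1 <- one_gene_config(1, 10, 10)
  cfg1$allele_freqs$DRB1[] <- 0
  cfg1$allele_freqs$DRB1["15:01"] <- 1
  h1 <- simulate_haplotypes(cfg1, 50)
  expect_true(all(h1[, "DRB1"] == "15:01"))
  # configured DR15 coupling is realized at the residue level
  x <- as.integer(haps[, "DRB1"] == "15:01")
  y <- as.integer(haps[, "DQB1"] == "06:02")
  expect_lt(abs(cor(x, y)^2 - 0.92), 0.05)
})

test_that("couple_alleles reproduces the closed-form joint table", {
  fA <- c(a = 0.3, b = 0.7); fB <- c(u = 0.4, v = 0.6)
  tab <- couple_alleles(fA, fB, "a", "u", 0.5)
  expect_equal(sum(tab$freq), 1, tolerance = 1e-12)
  # margins preserved
  expect_equal(sum(tab$freq[tab$a1 == "a"]), 0.3, tolerance = 1e-12)
  expect_equal(sum(tab$freq[tab$a2 == "u"]), 0.4, tolerance = 1e-12)
  # achieved r2 equals the request
  fab <- tab$freq[tab$a1 == "a" & tab$a2 == "u"]
  r2 <- (fab - 0.3 * 0.4)^2 / (0.3 * 0.7 * 0.4 * 0.6)
  expect_equal(r2, 0.5, tolerance = 1e-10)
  expect_error(couple_alleles(c(a = 0.01, b = 0.99), c(u = 0.9, v = 0.1),
                              "a", "u", 0.9), "unattainable")
})

test_that("residue dosages are exact allele sums before noise", {
  sim <- simulate_cohort(toy_asia_config(seed = 8, scale = 0.05))
  map <- toy_allele_map()
  dm <- sim$dosage_true
  # DRB1-13 R is carried by 15:01 alone in the bundled map
  expect_equal(dm$dosage[, "AA_DRB1_13_32546583_R"],
               dm$dosage[, "HLA_DRB1_1501"])
  # DRB1-11 S sums the dosages of every S-carrying allele
  s_alleles <- map$allele[map$gene == "DRB1" & map$aa_pos == 11 &
                          map$residue == "S"]
  ids <- sprintf("HLA_DRB1_%s", gsub(":", "", s_alleles))
  expect_equal(dm$dosage[, "AA_DRB1_11_32546577_S"],
               rowSums(dm$dosage[, ids]))
})

test_that("status intercept calibration hits the requested case fraction", {
  cfg <- one_gene_config(21, 2000, 8000,
                         causal = data.frame(gene = "DRB1", aa_pos = 13,
                                             residue = "R", beta = log(1.5)),
                         sex_beta = log(3))
  sim <- simulate_cohort(cfg)
  frac <- mean(sim$panel$status)
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(frac - 0.2), 3 * se)
  # all-null model: planted-marker case/control difference is noise-level
  cfg0 <- one_gene_config(22, 1000, 1000)
  sim0 <- simulate_cohort(cfg0)
  d13 <- sim0$dosage$dosage[, "AA_DRB1_13_32546583_R"]
  expect_lt(abs(mean(d13[sim0$panel$status == 1]) -
                mean(d13[sim0$panel$status == 0])), 0.05)
})

test_that("a planted residue effect is recovered as its allelic odds ratio", {
  # average the estimator over replicates so the +/-0.1 band sits at ~3 SE
  ors <- vapply(31:35, function(s) {
    cfg <- one_gene_config(s, 5000, 5000,
                           causal = data.frame(gene = "DRB1", aa_pos = 13,
                                               residue = "R",
                                               beta = log(1.57)))
    sim <- simulate_cohort(cfg)
    fit_biallelic(sim$dosage$dosage[, "AA_DRB1_13_32546583_R"], sim$panel)$or
  }, numeric(1))
  expect_lt(abs(mean(ors) - 1.57), 0.1)
})

test_that("imputation noise is tuned to the target r2 and clipped", {
  cfg <- one_gene_config(41, 5000, 5000)
  sim <- simulate_cohort(cfg)
  dm <- sim$dosage_true
  set.seed(7)
  noisy <- add_imputation_noise(dm, default_r2 = 0.8)
  aa <- dm$markers$id[dm$markers$kind == "AA"]
  common <- aa[colMeans(dm$dosage[, aa] >= 0.5) > 0.1]
  realized <- vapply(common, function(id)
    cor(dm$dosage[, id], noisy$dosage[, id])^2, numeric(1))
  expect_true(all(realized > 0.77 & realized < 0.83))
  expect_equal(noisy$markers$r2[match(common, noisy$markers$id)],
               unname(realized))
  expect_true(all(noisy$dosage >= 0 & noisy$dosage <= 2))
  # r2 = 1 leaves dosages untouched
  expect_identical(add_imputation_noise(dm, default_r2 = 1)$dosage, dm$dosage)
})

test_that("sub-phenotypes are case-only and recover the planted case-only OR", {
  sp <- list(nRNP = list(baseline = 0.372,
                         effects = data.frame(gene = "DRB1", aa_pos = 11,
                                              residue = "D",
                                              beta = log(1.8))),
             La = list(baseline = 0.25, effects = NULL))
  cfg <- one_gene_config(51, 2000, 200, subpheno = sp)
  sim <- simulate_cohort(cfg)
  p <- sim$panel
  expect_true(all(is.na(p$nRNP[p$status == 0])))
  expect_true(all(is.na(p$La[p$status == 0])))
  # zero-effect antibody sits at its baseline
  expect_lt(abs(mean(p$La[p$status == 1], na.rm = TRUE) - 0.25), 0.05)
  # planted effect recovered by case-only fits (each stratum mirrors the
  # ~700/1150 positive/negative scale; averaged so +/-0.15 sits at ~2 SE)
  case_only_or <- function(seed) {
    simr <- simulate_cohort(one_gene_config(seed, 2000, 200, subpheno = sp))
    pr <- simr$panel
    cases <- pr$status == 1 & !is.na(pr$nRNP)
    p2 <- pr[cases, ]; p2$status <- p2$nRNP
    fit_biallelic(simr$dosage$dosage[cases, "AA_DRB1_11_32546577_D"], p2)$or
  }
  ors <- vapply(52:57, case_only_or, numeric(1))
  expect_lt(abs(mean(ors) - 1.8), 0.15)
})

test_that("configs survive the YAML round trip", {
  cfg <- recovery_config(3, 50, 50)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    seed = 3,
    cohorts = list(C1 = list(n_cases = 50, n_controls = 50)),
    allele_freqs = lapply(cfg$allele_freqs, as.list),
    allele_map = apply(cfg$allele_map, 1, as.list),
    causal_effects = apply(cfg$causal_effects, 1, as.list),
    snp_tags = FALSE), f)
  cfg2 <- read_sim_config(f)
  expect_s3_class(cfg2, "sim_config")
  sim <- simulate_cohort(cfg2)
  expect_equal(nrow(sim$panel), 100)
})
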