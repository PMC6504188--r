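test_that("biallelic fits recover planted effects and flag degenerate markers", {
  cfg <- one_gene_config(101, 2000, 2000,
                         causal = data.frame(gene = "DRB1", aa_pos = 13,
                                             residue = "R", beta = log(1.5)))
  sim <- simulate_cohort(cfg)
  r <- fit_biallelic(sim$dosage$dosage[, "AA_DRB1_13_32546583_R"], sim$panel)
  expect_true(is.na(r$reason))
  expect_lt(abs(r$beta - log(1.5)), 3 * r$se)
  expect_equal(r$or, exp(r$beta))
  expect_true(r$lci < r$or && r$or < r$uci)

  rmono <- fit_biallelic(rep(1, nrow(sim$panel)), sim$panel)
  expect_equal(rmono$reason, "monomorphic")
  expect_true(is.na(rmono$p))
})

test_that("covariate-free logistic on a collapsed 2x2 table equals the crude OR", {
  # 2x2 of carrier counts: cases 150/350, controls 100/400
  d <- c(rep(1, 150), rep(0, 350), rep(1, 100), rep(0, 400))
  y <- c(rep(1, 500), rep(0, 500))
  panel <- as_panel(data.frame(individual_id = sprintf("I%04d", 1:1000),
                               status = y, sex = 0, pc1 = 0, pc2 = 0, pc3 = 0,
                               cohort = "C1"))
  r <- fit_biallelic(d, panel, covariates = FALSE)
  crude <- (150 / 350) / (100 / 400)
  expect_equal(signif(r$or, 4), signif(crude, 4))
})

test_that("crude allelic odds ratios match the printed contrasts", {
  expect_equal(round(crude_allelic_or(0.159, 0.094), 2), 1.82)
  expect_equal(round(crude_allelic_or(0.200, 0.204), 2), 0.98)
  expect_equal(crude_allelic_or(0.3, 0.3), 1)
  expect_error(crude_allelic_or(0, 0.5), "strictly inside")
  expect_error(crude_allelic_or(0.5, 1), "strictly inside")
})

test_that("a 2-residue omnibus test reduces to the biallelic LRT", {
  set.seed(71)
  cc <- draw_position_cohort(800, c(R = 0.3, S = 0.7))
  om <- omnibus_test(cc$position, cc$dm, cc$panel)
  expect_equal(om$df, 1L)
  # independent two-model ML oracle via glm()
  dat <- data.frame(y = cc$panel$status, d = cc$dm$dosage[, 1],
                    sex = cc$panel$sex, pc1 = cc$panel$pc1,
                    pc2 = cc$panel$pc2, pc3 = cc$panel$pc3)
  m0 <- glm(y ~ sex + pc1 + pc2 + pc3, data = dat, family = binomial())
  m1 <- glm(y ~ sex + pc1 + pc2 + pc3 + d, data = dat, family = binomial())
  D_oracle <- as.numeric(2 * (logLik(m1) - logLik(m0)))
  p_oracle <- pchisq(D_oracle, 1, lower.tail = FALSE)
  expect_equal(om$D, D_oracle, tolerance = 1e-8)
  expect_equal(om$p, p_oracle, tolerance = 1e-10 * p_oracle + 1e-300)
})

test_that("omnibus is invariant to residue relabeling and reference dropping", {
  set.seed(72)
  cc <- draw_position_cohort(600, c(A = 0.4, D = 0.3, S = 0.2, W = 0.1))
  om1 <- omnibus_test(cc$position, cc$dm, cc$panel)
  expect_gte(om1$D, 0)
  # relabel the residues (permute columns + rename): D and p unchanged
  dm2 <- cc$dm
  perm <- c(3, 1, 4, 2)
  d2 <- dm2$dosage[, perm]
  colnames(d2) <- colnames(cc$dm$dosage)[perm]
  dm2 <- hla_dosage(d2, rep(1, 4))
  om2 <- omnibus_test(group_positions(dm2)[[1]], dm2, cc$panel)
  expect_equal(om1$D, om2$D, tolerance = 1e-8)
  expect_equal(om1$p, om2$p, tolerance = 1e-8 * om1$p)
  # adding a redundant (collinear) residue column leaves p invariant
  d3 <- cbind(cc$dm$dosage,
              "AA_DRB1_13_32546583_x" = 2 - rowSums(cc$dm$dosage))
  dm3 <- hla_dosage(d3, rep(1, 5))
  om3 <- omnibus_test(group_positions(dm3)[[1]], dm3, cc$panel)
  expect_equal(om3$df, om1$df)
  expect_equal(om3$p, om1$p, tolerance = 1e-6 * om1$p)
})

test_that("conditioning a causal position on itself removes its signal", {
  cfg <- recovery_config(73, 1500, 1500, beta_b_9D = 0)
  sim <- simulate_cohort(cfg)
  pos <- group_positions(sim$dosage)
  p13 <- pos[[grep("DRB1_13", names(pos))]]
  om <- omnibus_test(p13, sim$dosage, sim$panel)
  expect_lt(om$p, 1e-4)
  V <- sim$dosage$dosage[, p13$marker_ids]
  omc <- omnibus_test(p13, sim$dosage, sim$panel, conditioning = V)
  expect_equal(omc$df, 0L)
  expect_equal(omc$p, 1)
})

test_that("gene allele blocks fully explain their own residues", {
  cfg <- recovery_config(74, 800, 800)
  sim <- simulate_cohort(cfg)
  blk <- condition_on_gene_alleles("DRB1", sim$dosage_true)
  expect_equal(ncol(blk), 5L)  # 6 alleles minus reference
  # noiseless residues are exact linear combinations of the allele block
  res_ids <- sim$dosage_true$markers$id[
    sim$dosage_true$markers$kind == "AA" &
    sim$dosage_true$markers$gene == "DRB1"]
  X <- cbind(1, blk)
  for (id in res_ids) {
    fit <- lm.fit(X, sim$dosage_true$dosage[, id])
    expect_lt(sum(fit$residuals^2), 1e-18)
  }
  # hence every DRB1 omnibus test conditioned on the block is null
  pos <- group_positions(sim$dosage_true)
  for (k in grep("^DRB1_", names(pos), value = TRUE)) {
    om <- omnibus_test(pos[[k]], sim$dosage_true, sim$panel,
                       conditioning = blk)
    expect_gt(om$p, 0.05)
  }
  expect_error(condition_on_gene_alleles("DPA1", sim$dosage), "fewer than two")
})

test_that("omnibus p-values are uniform under the null", {
  set.seed(75)
  pvals <- replicate(200, {
    cc <- draw_position_cohort(250, c(A = 0.35, D = 0.3, S = 0.25, W = 0.1))
    omnibus_test(cc$position, cc$dm, cc$panel)$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the stepwise scan returns nothing on a null cohort", {
  cfg <- recovery_config(76, 800, 800, beta_drb1_13R = 0, beta_b_9D = 0)
  sim <- simulate_cohort(cfg)
  sc <- stepwise_scan(sim$dosage, sim$panel)
  expect_equal(nrow(sc$selected), 0L)
  expect_true(nrow(sc$ledger) > 0)
})

test_that("allele-only effects stop the scan after that gene's stage B", {
  # plant a pure DRB1 signal; B must stay quiet after DRB1 conditioning
  cfg <- recovery_config(77, 3000, 3000, beta_b_9D = 0)
  sim <- simulate_cohort(cfg)
  sc <- stepwise_scan(filter_markers(sim$dosage), sim$panel)
  expect_true(all(sc$selected$gene == "DRB1"))
})

test_that("sub-phenotype contrasts partition cases and respect the stratum guard", {
  sp <- list(nRNP = list(baseline = 0.4,
                         effects = data.frame(gene = "DRB1", aa_pos = 11,
                                              residue = "D", beta = log(1.8))),
             La = list(baseline = 0.3, effects = NULL))
  cfg <- one_gene_config(78, 1400, 700, subpheno = sp)
  sim <- simulate_cohort(cfg)
  res <- subphenotype_contrasts(sim$dosage, sim$panel, "nRNP", markers = TRUE)
  mk <- res$case_only$markers
  r11 <- mk[mk$marker == "AA_DRB1_11_32546577_D", ]
  expect_lt(abs(r11$or - 1.8), 0.2)
  # negative-vs-control contrast shows no inflated risk at the planted marker
  mkn <- res$neg_vs_control$markers
  r11n <- mkn[mkn$marker == "AA_DRB1_11_32546577_D", ]
  expect_lt(r11n$or, 1.1)
  # partition: strata sizes add up to all antibody-typed cases
  typed <- sum(sim$panel$status == 1 & !is.na(sim$panel$nRNP))
  expect_equal(r11$n_cases + r11$n_controls, typed)
  # null antibody: case-only omnibus p-values stay non-degenerate
  res_la <- subphenotype_contrasts(sim$dosage, sim$panel, "La", markers = FALSE)
  expect_gt(min(res_la$case_only$omnibus$p), 1e-4)
  # stratum guard
  cfg_small <- one_gene_config(79, 60, 60,
                               subpheno = list(nRNP = list(baseline = 0.5,
                                                           effects = NULL)))
  sim_small <- simulate_cohort(cfg_small)
  expect_error(subphenotype_contrasts(sim_small$dosage, sim_small$panel,
                                      "nRNP"), "stratum too small")
})

test_that("linear conditioning explains simulated expression exactly when it should", {
  cfg <- one_gene_config(80, 1000, 1000)
  sim <- simulate_cohort(cfg)
  dm <- sim$dosage_true
  ids <- c("AA_DRB1_11_32546577_S", "AA_DRB1_13_32546583_R",
           "AA_DRB1_37_32546655_Y")
  set.seed(880)   # distinct from the cohort seed: the noise must be
                  # independent of the genotype draws
  expr <- dm$dosage[, ids] %*% c(0.5, -0.8, 0.3) + rnorm(2000, 0, 0.5)
  res <- linear_conditioning(as.numeric(expr), dm)
  expect_lt(min(res$p[res$marker %in% ids], na.rm = TRUE), 1e-20)
  # conditioning on the three causal residues silences every marker: none
  # stays significant at a Bonferroni-corrected 0.05
  resc <- linear_conditioning(as.numeric(expr), dm,
                              conditioning = dm$dosage[, ids])
  expect_gt(min(resc$p, na.rm = TRUE) * sum(!is.na(resc$p)), 0.05)
  # an irrelevant conditioning marker leaves the signal genome-wide strong
  resi <- linear_conditioning(as.numeric(expr), dm,
                              conditioning = dm$dosage[, "HLA_DRB1_0701",
                                                       drop = FALSE])
  expect_lt(resi$p[resi$marker == "AA_DRB1_13_32546583_R"], 5e-8)
  # zero-noise univariate fit has R2 = 1
  y0 <- 2 * dm$dosage[, ids[1]] + 1
  res0 <- linear_conditioning(y0, dm)
  expect_equal(res0$r2_model[res0$marker == ids[1]], 1, tolerance = 1e-9)
})

test_that("Wald and LRT p-values agree in order of magnitude for moderate effects", {
  cfg <- one_gene_config(81, 1500, 1500,
                         causal = data.frame(gene = "DRB1", aa_pos = 13,
                                             residue = "R", beta = log(1.2)))
  sim <- simulate_cohort(cfg)
  d <- sim$dosage$dosage[, "AA_DRB1_13_32546583_R"]
  r <- fit_biallelic(d, sim$panel)
  dat <- data.frame(y = sim$panel$status, d = d, sex = sim$panel$sex,
                    pc1 = sim$panel$pc1, pc2 = sim$panel$pc2,
                    pc3 = sim$panel$pc3)
  m0 <- glm(y ~ . - d, data = dat, family = binomial())
  m1 <- glm(y ~ ., data = dat, family = binomial())
  p_lrt <- pchisq(2 * as.numeric(logLik(m1) - logLik(m0)), 1,
                  lower.tail = FALSE)
  expect_lt(abs(r$beta / r$se), 5)
  expect_lt(abs(log10(r$p) - log10(p_lrt)), 1)
})

test_that("planted positions are recovered by the conditional scan", {
  cfg <- recovery_config(82, 5000, 5000)
  sim <- simulate_cohort(cfg)
  sc <- stepwise_scan(filter_markers(sim$dosage), sim$panel)
  key <- paste0(sc$selected$gene, "-", sc$selected$aa_pos)
  expect_equal(key[1], "DRB1-13")
  expect_true("B-9" %in% key)
  expect_true(all(key %in% c("DRB1-13", "B-9")))
})
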