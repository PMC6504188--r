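test_that("liability variance behaves as the threshold model dictates", {
  expect_equal(vg_from_or(0.3, 1, 0.001), 0, tolerance = 1e-12)
  vals <- vapply(c(1.1, 1.3, 1.5, 2), function(o) vg_from_or(0.3, o, 0.001),
                 numeric(1))
  expect_true(all(diff(vals) > 0))   # strictly increasing in OR
  expect_error(vg_from_or(0, 1.5, 0.001), "raf")
  expect_error(vg_from_or(0.3, -1, 0.001), "positive")
  expect_error(vg_from_or(0.3, 1.5, 0), "prevalence")
})

test_that("Vg matches the numerical liability-integral oracle", {
  cases <- expand.grid(raf = c(0.1, 0.3, 0.45),
                       or = c(1.2, 1.5, 2.4),
                       K = c(0.001, 0.01))
  for (i in seq_len(nrow(cases))) {
    v <- vg_from_or(cases$raf[i], cases$or[i], cases$K[i])
    o <- oracle_vg(cases$raf[i], cases$or[i], cases$K[i])
    expect_equal(signif(v, 3), signif(o, 3))
  }
})

test_that("Vg is symmetric under risk/protective allele swap", {
  v1 <- vg_from_or(0.3, 1.5, 0.001)
  v2 <- vg_from_or(0.7, 1 / 1.5, 0.001)
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("total heritability sums per-residue Vg with proxy exclusion", {
  set.seed(61)
  tab <- data.frame(name = paste0("r", 1:7),
                    raf = runif(7, 0.1, 0.4),
                    or = runif(7, 1.1, 1.6))
  h <- total_heritability(tab, K = 0.001)
  indiv <- sum(mapply(oracle_vg, tab$raf, tab$or, MoreArgs = list(K = 0.001)))
  expect_equal(h$percent, 100 * indiv, tolerance = 1e-6 * indiv * 100)
  # a tightly linked proxy is excluded from the total
  tab2 <- rbind(tab, data.frame(name = "r1_proxy", raf = tab$raf[1],
                                or = tab$or[1]))
  tab2$proxy_of <- c(rep(NA, 7), "r1")
  h2 <- total_heritability(tab2, K = 0.001)
  expect_equal(h2$percent, h$percent, tolerance = 1e-12)
})

test_that("hard calls round dosages and mask uncertain genotypes", {
  d <- matrix(c(2.0, 1.5, 0.1, 0.85, 1.02, 1.25), nrow = 2)
  g <- hard_call(d, certainty_min = 0.8)
  expect_equal(g[1, ], c(2L, 0L, 1L))
  expect_true(is.na(g[2, 1]))   # dosage 1.5: certainty 0.5 < 0.8
  expect_equal(g[2, 2], 1L)
  expect_true(is.na(g[2, 3]))   # dosage 1.25: certainty 0.75
  # noiseless dosages are never masked
  sim <- simulate_cohort(toy_asia_config(seed = 62, scale = 0.05))
  calls <- hard_call(sim$dosage_true$dosage)
  expect_false(anyNA(calls))
})

test_that("burden bin odds ratios are exact contingency arithmetic", {
  # bin 0: 100 cases / 200 controls; bin 3: 200 cases / 100 controls
  calls <- matrix(0L, 600, 3)
  calls[301:600, ] <- 1L
  y <- c(rep(1, 100), rep(0, 200), rep(1, 200), rep(0, 100))
  panel <- as_panel(data.frame(individual_id = sprintf("I%03d", 1:600),
                               status = y, sex = 0, pc1 = 0, pc2 = 0, pc3 = 0,
                               cohort = "C1"))
  bt <- burden_analysis(calls, panel, auc = FALSE)
  expect_equal(bt$bins$or[bt$bins$count == 0], 1)
  expect_equal(bt$bins$or[bt$bins$count == 3], 4.0, tolerance = 1e-12)
  # bin ORs equal covariate-free logistic fits on the collapsed indicator
  ind <- as.integer(rowSums(calls) == 3)
  r <- fit_biallelic(ind, panel, covariates = FALSE)
  expect_equal(bt$bins$or[bt$bins$count == 3], r$or, tolerance = 1e-6)
})

test_that("identical case/control count distributions give flat burden", {
  set.seed(63)
  calls <- matrix(rbinom(2000 * 5, 2, 0.25), 2000, 5)
  y <- rep(c(1, 0), 1000)   # status independent of counts
  panel <- as_panel(data.frame(individual_id = sprintf("I%04d", 1:2000),
                               status = y, sex = 0, pc1 = 0, pc2 = 0, pc3 = 0,
                               cohort = "C1"))
  bt <- burden_analysis(calls, panel, auc = FALSE)
  expect_lt(abs(bt$linear_fit$slope), 0.15)
  expect_true(all(abs(bt$bins$or - 1) < 0.6, na.rm = TRUE))
})

test_that("additive simulations look additive: linear OR growth, additive AIC wins", {
  set.seed(64)
  n <- 10000
  calls <- matrix(rbinom(n * 7, 2, 0.15), n, 7)
  lp <- log(1.3) * rowSums(calls) - 1.6
  y <- rbinom(n, 1, plogis(lp))
  panel <- as_panel(data.frame(individual_id = sprintf("I%05d", 1:n),
                               status = y, sex = 0, pc1 = 0, pc2 = 0, pc3 = 0,
                               cohort = "C1"))
  bt <- burden_analysis(calls, panel, auc = TRUE)
  expect_gte(bt$linear_fit$r2, 0.85)
  expect_lte(bt$aic_additive, bt$aic_interaction)
  # ROC machinery: both scores discriminate, comparison p is a valid p-value
  expect_gt(bt$auc_weighted, 0.55)
  expect_gt(bt$auc_unweighted, 0.55)
  expect_true(bt$auc_p > 0 && bt$auc_p <= 1)
})

test_that("the reference bin must be occupied", {
  calls <- matrix(1L, 50, 2)
  panel <- as_panel(data.frame(individual_id = sprintf("I%02d", 1:50),
                               status = rep(c(0, 1), 25), sex = 0,
                               pc1 = 0, pc2 = 0, pc3 = 0, cohort = "C1"))
  expect_error(burden_analysis(calls, panel, auc = FALSE), "reference bin")
})
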