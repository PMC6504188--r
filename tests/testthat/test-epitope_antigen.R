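pot <- load_contact_potential()

test_that("the packaged potential is a valid symmetric 20x20 table", {
  expect_equal(dim(pot), c(20L, 20L))
  expect_equal(pot, t(pot))
  expect_false(anyNA(pot))
})

test_that("preference scores are linear, antisymmetric, and zero for empty lists", {
  sle <- residue_lists("SLE")
  s1 <- preference_scores(pot, sle)
  s2 <- preference_scores(2.5 * pot, sle)
  expect_equal(s2$score_sum, 2.5 * s1$score_sum, tolerance = 1e-9)
  # swapping the lists negates score_sum
  swapped <- list(immunogenic = sle$non_immunogenic,
                  non_immunogenic = sle$immunogenic)
  s3 <- preference_scores(pot, swapped)
  m <- match(s1$aa, s3$aa)
  expect_equal(s3$score_sum[m], -s1$score_sum, tolerance = 1e-9)
  s0 <- preference_scores(pot, list(immunogenic = character(0),
                                    non_immunogenic = character(0)))
  expect_true(all(s0$score_sum == 0))
  expect_error(preference_scores(pot, list(immunogenic = "W",
                                           non_immunogenic = "W")),
               "disjoint")
})

test_that("SLE and RA rankings reproduce the published group orderings", {
  sle <- preference_scores(pot, residue_lists("SLE"))
  top9 <- sle$aa[1:9]; bottom9 <- sle$aa[12:20]; mid <- sle$aa[10:11]
  expect_setequal(top9, c("W", "I", "F", "L", "E", "Y", "P", "M", "D"))
  expect_setequal(bottom9, c("T", "G", "S", "C", "N", "K", "Q", "H", "R"))
  expect_setequal(mid, c("A", "V"))
  ra <- preference_scores(pot, residue_lists("RA"))
  expect_setequal(ra$aa[1:9], c("K", "R", "I", "L", "F", "A", "M", "V", "P"))
  expect_setequal(ra$aa[14:20], c("D", "E", "G", "Q", "N", "Y", "T"))
  # strict profile ordering: the seven strict risk residues all rank above
  # the five strict protective residues
  strict_risk <- c("W", "I", "F", "L", "E", "Y", "D")
  strict_prot <- c("R", "S", "N", "K", "T")
  expect_lt(max(match(strict_risk, sle$aa)), min(match(strict_prot, sle$aa)))
})

test_that("classification cuts the ranking at the requested sizes", {
  sle <- preference_scores(pot, residue_lists("SLE"))
  all_risk <- classify(sle, n_risk = 20, n_protective = 0)
  expect_true(all(all_risk$class == "risk"))
  none <- classify(sle, n_risk = 0, n_protective = 0)
  expect_true(all(none$class == "intermediate"))
  broad <- classify(sle, 9, 9)
  expect_equal(sum(broad$class == "risk"), 9L)
  expect_equal(sum(broad$class == "protective"), 9L)
  expect_equal(sum(broad$class == "intermediate"), 2L)
  expect_error(classify(sle, 15, 15), "<= 20")
})

test_that("overlap counts match the published tallies", {
  ra <- classify(preference_scores(pot, residue_lists("RA")), 9, 9)
  ra_risk_set <- ra$aa[ra$class == "risk"]
  # the seven experimentally residue-mapped RA risk side-chains
  ov <- overlap_count(ra_risk_set, c("V", "L", "K", "R", "A", "D", "F"))
  expect_equal(ov$count, 6L)
  expect_equal(ov$expected, 7 * 9 / 20)
  # autoantibody tallies against the strict predicted sets
  strict_risk <- c("W", "I", "F", "L", "E", "Y", "D")
  strict_prot <- c("R", "S", "N", "K", "T")
  risk_obs <- c("G", "D", "F", "G", "D", "D", "L")
  prot_obs <- c("H", "S", "S", "F", "R", "V", "G")
  expect_equal(overlap_count(strict_risk, risk_obs)$count, 5L)
  expect_equal(overlap_count(strict_prot, prot_obs)$count, 3L)
  expect_equal(overlap_count(character(0), risk_obs)$count, 0L)
  expect_equal(overlap_count(character(0), risk_obs)$expected, 0)
})

test_that("protein profiles follow the charge model", {
  g5 <- protein_profile("GGGGG")
  expect_lt(abs(g5$charge), 0.2)       # termini near-cancel at pH 7
  k10 <- protein_profile("KKKKKKKKKK")
  expect_gt(k10$pI, 9)
  expect_gt(k10$charge_per_residue, 0)
  expect_equal(k10$n_K, 10)
  # pI is the unique zero crossing of a monotone charge-pH curve
  p <- protein_profile("ACDEFGHIKLMNPQRSTVWY")
  expect_lt(abs(protein_profile(p$sequence, pH = p$pI)$charge), 1e-3)
  expect_gt(protein_profile(p$sequence, pH = p$pI - 1)$charge, 0)
  expect_lt(protein_profile(p$sequence, pH = p$pI + 1)$charge, 0)
  expect_equal(p$charge_per_residue, p$charge / p$length)
  expect_error(protein_profile("ACDEFZ"), "positions: 6")
})

test_that("citrullination replaces arginines by glutamines and drops charge", {
  r <- protein_profile("ARKA")
  c1 <- citrullinate(r)
  expect_equal(c1$sequence, "AQKA")
  expect_lt(c1$charge - r$charge, -0.9)
  expect_gt(c1$charge - r$charge, -1.1)
  # idempotent, and a no-op without arginines
  expect_equal(citrullinate(c1)$sequence, c1$sequence)
  nr <- protein_profile("GSTA")
  expect_equal(citrullinate(nr)$sequence, "GSTA")
  # poly-R: citrullination lowers the isoelectric point
  rr <- protein_profile("RRRRRRRR")
  expect_lt(citrullinate(rr)$pI, rr$pI)
})

test_that("FASTA profiling returns one row per protein (plus citrullinated)", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">toy_basic", "KKKRRKKA", ">toy_acidic", "DDEEDDGG"), f)
  prof <- profile_fasta(f, citrullinated = TRUE)
  expect_equal(nrow(prof), 4L)
  expect_gt(prof$charge[prof$name == "toy_basic"], 0)
  expect_lt(prof$charge[prof$name == "toy_acidic"], 0)
  cit <- prof[prof$name == "toy_basic_citrullinated", ]
  expect_lt(cit$charge, prof$charge[prof$name == "toy_basic"])
})
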