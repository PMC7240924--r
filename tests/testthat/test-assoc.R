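test_that("expected counts follow the subset's overall phenotype rate", {
  counts <- data.frame(class = c("AA", "BB"),
                       obs_sus = c(50L, 30L), obs_res = c(50L, 70L))
  gt <- gt_from_counts(counts)
  exp_all <- expected_counts(gt, "all")
  # overall sus rate 80/200 = 0.4
  expect_equal(exp_all$exp_sus[exp_all$class == "AA"], 40)
  expect_equal(exp_all$exp_res[exp_all$class == "AA"], 60)
  # conservation: expected susceptible totals the observed susceptible
  expect_equal(sum(exp_all$exp_sus), sum(exp_all$obs_sus))
  # single-genotype population: expected equals observed
  solo <- gt_from_counts(data.frame(class = "AA", obs_sus = 3L,
                                    obs_res = 7L))
  exp_solo <- expected_counts(solo, "all")
  expect_equal(exp_solo$exp_sus, 3)
  expect_equal(exp_solo$exp_res, 7)
  expect_error(expected_counts(solo, "male"), "empty")
})

test_that("reconstructed female single-locus expectations match the oracle", {
  t2 <- load_fixture("table2_lrrtm4")
  fem <- t2[t2$subset == "female", ]
  res <- associate_counts(fem)
  # female overall susceptibility ~0.367 over 351 birds
  rate <- sum(fem$obs_sus) / sum(fem$obs_sus + fem$obs_res)
  expect_equal(rate, 0.367, tolerance = 0.005)
  expect_equal(res$exp_sus[res$class == "AG"], 41.5, tolerance = 0.01)
})

test_that("two-cell chi-square matches Excel CHITEST semantics", {
  z <- chi2_obs_vs_exp(c(10, 20), c(10, 20))
  expect_equal(unname(z), c(0, 1))
  z2 <- chi2_obs_vs_exp(c(112, 134), c(88.4, 157.6))
  expect_equal(z2[["chi2"]], 9.834, tolerance = 1e-3)
  expect_equal(z2[["p"]], 0.0017, tolerance = 0.05)
  expect_warning(z3 <- chi2_obs_vs_exp(c(5, 5), c(0, 10)), "untested")
  expect_true(all(is.nan(z3)))
})

test_that("chi-square equals an independent goodness-of-fit oracle", {
  set.seed(7L)
  for (i in 1:20) {
    obs <- sample(1:200, 2L)
    rate <- runif(1L, 0.1, 0.9)
    exp <- sum(obs) * c(rate, 1 - rate)
    mine <- chi2_obs_vs_exp(obs, exp)
    oracle <- suppressWarnings(stats::chisq.test(obs, p = exp / sum(exp)))
    expect_lt(abs(mine[["chi2"]] - unname(oracle$statistic)), 1e-12)
    expect_lt(abs(mine[["p"]] - oracle$p.value), 1e-12)
  }
})

test_that("association flags the published classes and only those", {
  t2 <- associate_counts(load_fixture("table2_lrrtm4"))
  sig <- t2[t2$significant, c("subset", "class")]
  expect_true(all(c("all", "female") %in% sig$subset))
  expect_equal(unique(sig$class), "AG")
  # no male single-locus class reaches significance
  expect_false(any(t2$significant[t2$subset == "male"]))
  # female adjusted P-values within 15% of the published 0.047/0.83/0.52
  fem <- t2[t2$subset == "female", ]
  printed <- c(AG = 0.047, RR = 0.83, GA = 0.52)
  expect_equal(fem$p_adj[match(names(printed), fem$class)],
               unname(printed), tolerance = 0.15)

  t3 <- associate_counts(load_fixture("table3_combined"))
  male_sig <- t3[t3$subset == "male" & t3$significant, ]
  expect_equal(male_sig$class, "RRCC")
  # the RRCC chi-square sits where the count-reconstruction oracle puts it
  expect_gt(male_sig$chi2, 8)
  expect_lt(male_sig$chi2, 10)
})

test_that("the class-frequency filter and Bonferroni scoping behave", {
  t3 <- associate_counts(load_fixture("table3_combined"))
  male <- t3[t3$subset == "male", ]
  expect_false(any(male$tested[male$freq <= 0.10]))
  expect_true(all(is.na(male$p_raw[!male$tested])))
  k <- sum(male$tested)
  expect_equal(male$p_adj, pmin(1, male$p_raw * k))
  expect_true(all(male$p_adj >= male$p_raw, na.rm = TRUE))
  expect_true(all(male$p_adj <= 1, na.rm = TRUE))
  expect_error(associate_counts(data.frame(subset = "all", class = "AA",
                                           obs_sus = 5L, obs_res = 5L)),
               "fewer than 2")
})

test_that("unknown-sex individuals count in 'all' only", {
  df <- data.frame(sample_id = sprintf("s%02d", 1:12),
                   sex = rep(c("male", "female", "unknown"), each = 4L),
                   phenotype = rep(c("resistant", "susceptible"), 6L),
                   LRRTM4 = rep(c("GA", "RR", "AG"), 4L))
  gt <- genotype_table(df, "LRRTM4")
  expect_equal(sum(expected_counts(gt, "all")$n), 12L)
  expect_equal(sum(expected_counts(gt, "male")$n), 4L)
  expect_equal(sum(expected_counts(gt, "female")$n), 4L)
})

test_that("HWE check recovers allele frequency and equilibrium fit", {
  h <- hwe_check(c(hom_ref = 25L, het = 50L, hom_alt = 25L))
  expect_equal(h$allele_freq, 0.5)
  expect_equal(unname(h$expected), c(0.25, 0.5, 0.25))
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  # monomorphic: degenerate but defined
  h0 <- hwe_check(c(hom_ref = 40L, het = 0L, hom_alt = 0L))
  expect_equal(h0$allele_freq, 0)
  expect_equal(h0$chi2, 0)
  # published whole-cohort counts are HWE-consistent
  t2 <- load_fixture("table2_lrrtm4")
  all_n <- setNames(t2$n[t2$subset == "all"][match(c("GA", "RR", "AG"),
                    t2$genotype[t2$subset == "all"])],
                    c("hom_ref", "het", "hom_alt"))
  h2 <- hwe_check(all_n)
  expect_equal(h2$allele_freq, 0.528, tolerance = 0.001)
  expect_gt(h2$p, 0.05)
})

test_that("two-locus tables combine on shared samples with composite labels", {
  a <- genotype_table(data.frame(sample_id = c("x", "y", "z"),
                                 phenotype = "resistant",
                                 LRRTM4 = c("RR", "GA", "AG")), "LRRTM4")
  b <- genotype_table(data.frame(sample_id = c("x", "y", "w"),
                                 phenotype = "resistant",
                                 CPQ = c("CC", "YM", "TA")), "CPQ")
  expect_message(ab <- combine_genotypes(a, b), "dropped")
  expect_equal(nrow(ab), 2L)
  expect_equal(sort(paste0(ab$LRRTM4, ab$CPQ)), c("GAYM", "RRCC"))
  # LRRTM4 het + CPQ hom-nonref composes to RRCC
  expect_equal(paste0(ab$LRRTM4[ab$sample_id == "x"],
                      ab$CPQ[ab$sample_id == "x"]), "RRCC")
  disj <- genotype_table(data.frame(sample_id = "q",
                                    phenotype = "susceptible",
                                    CPQ = "CC"), "CPQ")
  expect_warning(empty <- combine_genotypes(a, disj), "no shared")
  expect_equal(nrow(empty), 0L)
})

test_that("odds of resistance render as nearest-integer r:1", {
  o <- odds_of_resistance(52L, 9L)
  expect_equal(o$odds, 52 / 9, tolerance = 1e-12)
  expect_equal(o$label, "6:1")
  expect_equal(odds_of_resistance(50L, 50L)$label, "1:1")
  expect_equal(odds_of_resistance(0L, 5L)$odds, 0)
  expect_equal(odds_of_resistance(0L, 5L)$label, "0:1")
  expect_error(odds_of_resistance(5L, 0L), "positive")
})

test_that("null cohorts rarely flag classes; implanted effects are found", {
  a_null <- associate(null_cohort(n = 900L, seed = 41L))
  expect_equal(sum(a_null$significant), 0L)
  # implanted effect: hom-nonref susceptibility lifted by 25 points
  set.seed(42L)
  n <- 600L
  g <- sample(c("GA", "RR", "AG"), n, TRUE, prob = c(0.25, 0.5, 0.25))
  p_sus <- ifelse(g == "AG", 0.70, 0.45)
  df <- data.frame(sample_id = sprintf("e%03d", 1:n),
                   sex = sample(c("male", "female"), n, TRUE),
                   phenotype = ifelse(runif(n) < p_sus,
                                      "susceptible", "resistant"),
                   LRRTM4 = g)
  a_eff <- associate(genotype_table(df, "LRRTM4"))
  expect_true(a_eff$significant[a_eff$subset == "all" &
                                  a_eff$class == "AG"])
})
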