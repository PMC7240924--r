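test_that("identical configurations give bit-identical pool-seq tables", {
  cfg <- sim_config(n_individuals = 160L, n_neutral_snps = 300L, seed = 11L)
  a <- simulate_poolseq(cfg)
  b <- simulate_poolseq(cfg)
  expect_identical(a$counts$alt_count, b$counts$alt_count)
  expect_identical(a$counts$depth, b$counts$depth)
  expect_identical(a$counts$sites, b$counts$sites)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_poolseq(sim_config(n_individuals = 160L,
                                    n_neutral_snps = 300L, seed = 12L))
  expect_false(identical(a$counts$alt_count, c2$counts$alt_count))
})

test_that("null model hits the prevalence target exactly", {
  pop <- simulate_population(sim_config(n_individuals = 601L,
                                        n_neutral_snps = 10L,
                                        prevalence_target = 0.5, seed = 2L))
  # empirical-quantile thresholding fixes the susceptible count
  expect_equal(sum(pop$phenotype == "susceptible"), round(601 * 0.5))
})

test_that("founder genotypes are Hardy-Weinberg at the drawn frequency", {
  q <- qtl_spec("1", 1000L, 0.5)  # neutral: betas zero
  pop <- simulate_population(sim_config(n_individuals = 3000L,
                                        n_neutral_snps = 5L,
                                        qtls = list(q), seed = 5L))
  g <- pop$genotypes[which(pop$sites$qtl_id == 1L)[1L], ]
  freqs <- tabulate(g + 1L, 3L) / length(g)
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 3000)
  expect_true(all(abs(freqs - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("a male-specific positive-beta QTL depresses the male differential only", {
  q <- qtl_spec("1", 1000L, 0.5, beta_male = 2, beta_female = 0,
                n_snps = 5L, span_bp = 400L)
  sim <- simulate_poolseq(sim_config(n_individuals = 400L,
                                     n_neutral_snps = 50L,
                                     qtls = list(q), seed = 8L))
  # positive beta raises susceptibility, so resistant males carry fewer
  # alt alleles: d_male < 0, d_female ~ 0
  expect_lt(sim$truth$d_male, -0.15)
  expect_lt(abs(sim$truth$d_female), 0.15)
})

test_that("pools are disjoint draws of pool_size birds per cell", {
  cfg <- sim_config(n_individuals = 200L, n_neutral_snps = 20L, seed = 3L)
  pop <- simulate_population(cfg)
  ps <- make_pools(pop, cfg)
  expect_equal(nrow(ps$pools), 8L)
  expect_true(all(lengths(ps$members) == 10L))
  all_members <- unlist(ps$members)
  expect_equal(length(unique(all_members)), 80L)  # pairwise disjoint
  for (id in ps$pools$pool_id) {
    i <- match(id, ps$pools$pool_id)
    expect_true(all(pop$phenotype[ps$members[[id]]] ==
                      ps$pools$phenotype[i]))
    expect_true(all(pop$sex[ps$members[[id]]] == ps$pools$sex[i]))
  }
})

test_that("pool frequency is mean dosage over 2N", {
  cfg <- sim_config(n_individuals = 200L, n_neutral_snps = 20L, seed = 4L)
  pop <- simulate_population(cfg)
  # force degenerate genotypes to check the frequency arithmetic
  pop$genotypes[1L, ] <- 2L   # all hom_alt -> 1.0
  pop$genotypes[2L, ] <- 1L   # all het -> 0.5
  ps <- make_pools(pop, cfg)
  expect_true(all(ps$freq[1L, ] == 1))
  expect_true(all(ps$freq[2L, ] == 0.5))
})

test_that("infeasible pool demands fail early, naming the cell", {
  expect_error(sim_config(n_individuals = 79L), "infeasible")
  # few males: both male cells fall short of pool_size x n_replicates
  pop <- simulate_population(sim_config(n_individuals = 90L,
                                        male_fraction = 0.2,
                                        n_neutral_snps = 10L, seed = 1L))
  expect_error(make_pools(pop), "male")
})

test_that("read sampling is unbiased and reflects the error model", {
  cfg <- sim_config(n_individuals = 160L, n_neutral_snps = 1200L,
                    seq_error_rate = 0, seed = 6L)
  n_sites <- 1200L
  fake <- list(freq = matrix(0.5, n_sites, 8L,
                             dimnames = list(NULL, canonical_pools()$pool_id)),
               pools = canonical_pools(),
               sites = data.frame(chrom = "1", pos = seq_len(n_sites),
                                  ref = "A", alt = "G"))
  set.seed(9L)
  tab <- sample_reads(fake, cfg)
  frac <- sum(tab$alt_count) / sum(tab$depth)
  se <- sqrt(0.25 / sum(tab$depth))
  expect_lt(abs(frac - 0.5), 3 * se)

  fake$freq[] <- 0
  tab0 <- sample_reads(fake, cfg)
  expect_true(all(tab0$alt_count == 0L))  # f=0, e=0

  cfg_err <- sim_config(n_individuals = 160L, seq_error_rate = 0.01,
                        seed = 6L)
  set.seed(10L)
  tab_e <- sample_reads(fake, cfg_err)
  frac_e <- sum(tab_e$alt_count) / sum(tab_e$depth)
  expect_lt(abs(frac_e - 0.01), 3 * sqrt(0.01 * 0.99 / sum(tab_e$depth)))
})

test_that("implanted differentials are recovered within read-sampling error", {
  for (s in 1:3) {
    sim <- simulate_poolseq(qtl_sim_config(seed = s))
    tr <- diff_track(group_frequencies(sim$counts))
    dep <- attr(tr, "depth")
    site <- which(tr$chrom == sim$truth$chrom[1L] &
                    tr$pos == sim$truth$start_bp[1L])
    for (sx in c("male", "female")) {
      d_hat <- tr[[paste0("d_", sx)]][site]
      d_true <- sim$truth[[paste0("d_", sx)]][1L]
      dr <- dep[[sx]]$resistant[site]
      ds <- dep[[sx]]$susceptible[site]
      bound <- 3 * sqrt(0.25 * (1 / dr + 1 / ds))  # f(1-f) <= 1/4
      expect_lt(abs(d_hat - d_true), bound)
    }
  }
})

test_that("neutral-site differential tails match binomial sampling", {
  sim <- simulate_poolseq(sim_config(n_individuals = 160L,
                                     n_neutral_snps = 3000L, seed = 13L))
  tr <- diff_track(group_frequencies(sim$counts))
  # analytic null: var(d) ~ f(1-f)(1/10 + 2/(2*66)) per group pair, birds
  # plus reads; compare the observed exceedance of 0.20 against the
  # empirical normal prediction from the realized variance
  d <- tr$d_male[is.finite(tr$d_male)]
  p_hat <- mean(abs(d) > 0.20)
  p_pred <- 2 * stats::pnorm(-0.20, sd = stats::sd(d))
  se <- sqrt(p_pred * (1 - p_pred) / length(d))
  expect_lt(abs(p_hat - p_pred), 4 * se + 0.01)
})
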