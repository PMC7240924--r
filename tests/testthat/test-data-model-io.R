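test_that("pooled_snp_table enforces its invariants", {
  sites <- data.frame(chrom = "1", pos = c(300L, 100L), ref = "A", alt = "G")
  pools <- canonical_pools()
  tab <- pooled_snp_table(sites, pools, matrix(1L, 2, 8), matrix(2L, 2, 8))
  expect_equal(tab$sites$pos, c(100L, 300L))  # sorted on construction
  expect_equal(dim(tab), c(2L, 8L))

  expect_error(pooled_snp_table(sites, pools, matrix(70L, 2, 8),
                                matrix(66L, 2, 8)),
               "exceeds depth")
  dup <- data.frame(chrom = "1", pos = c(100L, 100L), ref = "A", alt = "G")
  expect_error(pooled_snp_table(dup, pools, matrix(1L, 2, 8),
                                matrix(2L, 2, 8)), "duplicate")
  same <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "A")
  expect_error(pooled_snp_table(same, pools, matrix(1L, 1, 8),
                                matrix(2L, 1, 8)), "differ")
})

test_that("sync dialect round-trips counts and coordinates exactly", {
  tab <- toy_counts(n_sites = 3L)
  tab$alt_count[] <- matrix(seq_len(24L), 3L)
  tab$depth[] <- tab$alt_count + 40L
  path <- withr::local_tempfile(fileext = ".sync.tsv")
  write_pooled_counts(tab, path)
  back <- read_pooled_counts(path, "sync")
  expect_equal(back$sites, tab$sites)
  expect_equal(back$alt_count, tab$alt_count)
  expect_equal(back$depth, tab$depth)
  expect_equal(back$pools$phenotype, tab$pools$phenotype)
  expect_equal(nrow(back$sites), 3L)
  expect_equal(nrow(back$pools), 8L)
})

test_that("malformed sync input fails with the offending line", {
  path <- withr::local_tempfile()
  writeLines(c("#chrom\tpos\tref\talt\tRM1\tSM1",
               "1\t100\tA\tG\t10:20\t5:30",
               "1\t200\tA\tG\t10:20"), path)
  expect_error(read_pooled_counts(path, "sync"), "line 3")

  writeLines(c("#chrom\tpos\tref\talt\tRM1\tSM1",
               "1\t100\tA\tG\t70:66\t5:30"), path)
  expect_error(read_pooled_counts(path, "sync"), "line 2")

  writeLines(c("#chrom\tpos\tref\talt\tRM1\tBAD1",
               "1\t100\tA\tG\t10:20\t5:30"), path)
  expect_error(read_pooled_counts(path, "sync"), "BAD1")
  # unknown id resolved by explicit pool metadata
  pools <- pool_spec(c("RM1", "BAD1"), c("resistant", "susceptible"),
                     c("male", "male"), c(1L, 1L))
  tab <- read_pooled_counts(path, "sync", pools = pools)
  expect_equal(unname(tab$alt_count[1L, ]), c(10L, 5L))
})

test_that("VCF allelic depths are parsed per pool", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "RM1\tSM1"),
    "22\t4405679\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/1:33,33\t0/0:60,6",
    "22\t4405681\t.\tG\tA,T\t.\tPASS\t.\tGT:AD\t0/1:30,30,6\t0/0:60,3,3",
    "22\t4405700\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/1:20,10\t./.:."), path)
  expect_warning(tab <- read_pooled_counts(path, "vcf"), "multi-allelic")
  expect_equal(nrow(tab$sites), 2L)  # multi-allelic record dropped
  expect_equal(unname(tab$alt_count[1L, "RM1"]), 33L)
  expect_equal(unname(tab$depth[1L, "RM1"]), 66L)
  expect_equal(unname(tab$depth[1L, "SM1"]), 66L)
  # missing AD => depth 0 there, site retained
  expect_equal(unname(tab$depth[2L, "SM1"]), 0L)
  expect_equal(unname(tab$alt_count[2L, "RM1"]), 10L)
})

test_that("bedGraph output is 0-based half-open, one line per SNP", {
  track <- make_track("22", 4405679L, d_male = 0.5)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_diff_track(track, path, "bedgraph")
  expect_equal(readLines(path), "22\t4405678\t4405679\t0.5")
  back <- read_diff_track(path, "bedgraph")
  expect_equal(back$pos, 4405679L)
  expect_equal(back$value, 0.5)

  empty <- make_track(character(), integer(), d_male = numeric())
  expect_error(write_diff_track(empty, path, "bedgraph"), "empty")
})

test_that("seg output is 1-based inclusive, keyed by sex, and round-trips", {
  track <- make_track("2", c(100L, 200L),
                      d_male = c(0.4, -0.3), d_female = c(0.1, NaN))
  path <- withr::local_tempfile(fileext = ".seg")
  write_diff_track(track, path, "seg")
  back <- read_diff_track(path, "seg")
  expect_equal(back$start, back$end)
  expect_equal(sort(unique(back$sample)), c("female", "male"))
  m <- back[back$sample == "male", ]
  expect_equal(m$start, c(100L, 200L))
  expect_equal(m$value, c(0.4, -0.3))
  expect_equal(back$value[back$sample == "female"], 0.1)  # NaN dropped
})

test_that("genotype tables validate labels, states and uniqueness", {
  df <- data.frame(sample_id = c("a", "b", "c"),
                   sex = c("male", "female", "unknown"),
                   phenotype = c("resistant", "susceptible", "resistant"),
                   LRRTM4 = c("GA", "RR", "AG"))
  gt <- genotype_table(df, "LRRTM4")
  expect_equal(genotype_state(gt$LRRTM4, "LRRTM4"),
               c("hom_ref", "het", "hom_alt"))
  expect_equal(genotype_label("hom_alt", "CPQ"), "CC")
  df$LRRTM4[2] <- "XX"
  expect_error(genotype_table(df, "LRRTM4"), "XX")
  df$LRRTM4[2] <- "RR"
  df$sample_id[2] <- "a"
  expect_error(genotype_table(df, "LRRTM4"), "unique")

  gt_path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(gt, gt_path)
  back <- read_genotype_table(gt_path, "LRRTM4")
  expect_equal(as.data.frame(back), as.data.frame(gt))
})

test_that("region fixture matches the published table", {
  regions <- load_fixture("table1_regions")
  expect_equal(nrow(regions), 28L)
  expect_equal(length(unique(regions$chrom)), 13L)
  r22 <- regions[regions$chrom == "22", ]
  expect_equal(r22$start_mbp, 4.40)
  expect_equal(r22$stop_mbp, 4.48)
  expect_equal(r22$male_diff_pct, 60)
  expect_equal(r22$female_diff_pct, 20)
  expect_equal(r22$genes, "LRRTM4")
  cpq <- regions[regions$chrom == "2" & regions$genes == "CPQ", ]
  expect_equal(c(cpq$male_diff_pct, cpq$female_diff_pct), c(40, 20))
})

test_that("genotype fixtures carry consistent printed percentages", {
  for (name in c("table2_lrrtm4", "table3_combined")) {
    tab <- load_fixture(name)
    expect_true(all(tab$pct_sus + tab$pct_res >= 99.8 &
                      tab$pct_sus + tab$pct_res <= 100.2))
    expect_true(all(abs(tab$obs_sus + tab$obs_res - tab$n) <= 1L))
  }
  t2 <- load_fixture("table2_lrrtm4")
  fem_ag <- t2[t2$subset == "female" & t2$genotype == "AG", ]
  expect_equal(fem_ag$n, 113L)
  expect_equal(c(fem_ag$pct_sus, fem_ag$pct_res), c(47.8, 52.2))
  t3 <- load_fixture("table3_combined")
  rrcc <- t3[t3$subset == "male" & t3$genotype == "RRCC", ]
  expect_equal(rrcc$n, 61L)
  expect_equal(c(rrcc$pct_sus, rrcc$pct_res), c(14.8, 85.2))
})
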