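# Builders for small in-memory objects shared across tests.

# A hand-written counts table over the canonical 8 pools.
toy_counts <- function(n_sites = 3L, depth = 66L, alt = 33L) {
  sites <- data.frame(chrom = "1", pos = seq(100L, by = 1000L,
                                             length.out = n_sites),
                      ref = "A", alt = "G")
  pools <- canonical_pools()
  pooled_snp_table(sites, pools,
                   matrix(alt, n_sites, 8L), matrix(depth, n_sites, 8L))
}

# Build a diff_track directly from per-site differentials.
make_track <- function(chrom, pos, d_male = NULL, d_female = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   stringsAsFactors = FALSE)
  if (!is.null(d_male)) df$d_male <- d_male
  if (!is.null(d_female)) df$d_female <- d_female
  structure(df, class = c("diff_track", "data.frame"))
}

# A genotype table expanded from per-class phenotype counts (single locus).
gt_from_counts <- function(counts, locus = "LRRTM4", sex = "unknown") {
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    n_sus <- counts$obs_sus[i]
    n_res <- counts$obs_res[i]
    data.frame(genotype = counts$class[i],
               phenotype = rep(c("susceptible", "resistant"),
                               c(n_sus, n_res)),
               stringsAsFactors = FALSE)
  }))
  rows$sample_id <- sprintf("s%04d", seq_len(nrow(rows)))
  rows$sex <- sex
  rows[[locus]] <- rows$genotype
  labs <- sort(unique(counts$class))
  map <- setNames(c(labs, paste0(".f", seq_len(3 - length(labs))))[1:3],
                  c("hom_ref", "het", "hom_alt"))
  genotype_table(rows, locus, code_maps = setNames(list(map), locus))
}

# Balanced null cohort: genotype independent of phenotype.
null_cohort <- function(n = 900L, seed = 1L) {
  set.seed(seed)
  df <- data.frame(
    sample_id = sprintf("b%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    phenotype = sample(c("resistant", "susceptible"), n, replace = TRUE),
    LRRTM4 = sample(c("GA", "RR", "AG"), n, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25)),
    stringsAsFactors = FALSE)
  genotype_table(df, "LRRTM4")
}

# Simulation settings used for caller sensitivity checks: one implanted
# QTL block of 40 linked SNPs with a strong sex-shared effect, which
# realizes Res-Sus differentials of magnitude ~0.4-0.6.
qtl_sim_config <- function(seed, beta = 2, n_snps = 40L) {
  q <- qtl_spec("2", 500000L, 0.5, beta_male = beta, beta_female = beta,
                n_snps = n_snps, span_bp = 30000L)
  sim_config(n_individuals = 400L, n_neutral_snps = 800L, qtls = list(q),
             seed = seed)
}
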