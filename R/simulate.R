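#' Specify a simulated QTL
#'
#' A QTL is a block of one or more perfectly linked SNPs (all copies of one
#' causal dosage) with sex-specific additive liability effects and an
#' optional epistatic partner locus. Effects are per alt-allele copy on the
#' liability scale; positive effects raise susceptibility, so the realized
#' Res-Sus frequency differential is negative for positive betas.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position of the block's first SNP.
#' @param alt_freq founder non-reference allele frequency, in (0, 1).
#' @param beta_male,beta_female liability effect per alt copy, by sex.
#' @param n_snps number of linked SNPs in the block (>= 1).
#' @param span_bp width of the block in bp (SNPs are evenly spaced over
#'   \code{[pos, pos + span_bp]}); 0 for a single site.
#' @param partner optional second \code{qtl_spec} (without its own partner)
#'   for an epistatic pair.
#' @param gamma interaction coefficient applied to the product of the two
#'   loci's alt dosages (requires \code{partner}); \code{gamma_female}
#'   defaults to \code{gamma} for a sex-shared interaction.
#' @param gamma_female optional female-specific interaction coefficient.
#' @return An object of class \code{qtl_spec}.
#' @export
qtl_spec <- function(chrom, pos, alt_freq, beta_male = 0, beta_female = 0,
                     n_snps = 1L, span_bp = 0L, partner = NULL, gamma = 0,
                     gamma_female = NULL) {
  stopifnot(alt_freq > 0, alt_freq < 1, is.finite(beta_male),
            is.finite(beta_female), n_snps >= 1L, span_bp >= 0L, pos >= 1)
  if (!is.null(partner)) {
    stopifnot(inherits(partner, "qtl_spec"))
    if (!is.null(partner$partner)) stop_("partner QTL cannot itself nest one")
  } else if (gamma != 0) stop_("gamma requires a partner locus")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 alt_freq = alt_freq, beta_male = beta_male,
                 beta_female = beta_female, n_snps = as.integer(n_snps),
                 span_bp = as.integer(span_bp), partner = partner,
                 gamma = gamma, gamma_female = gamma_female %||% gamma),
            class = "qtl_spec")
}

#' Default simulated chromosome layout
#'
#' Three desk-scale chromosomes with contrasting GC content, emulating the
#' macro/micro-chromosome GC spread of the chicken assembly at a size
#' tractable for tests.
#'
#' @return A \code{\link{chromosome_info}}.
#' @export
default_chromosomes <- function() {
  chromosome_info(name = c("1", "2", "3"),
                  length_bp = c(2e6, 1.5e6, 1e6),
                  gc_percent = c(42, 48, 56))
}

#' Simulation configuration
#'
#' Defaults mirror the pooled-resequencing study design: a hatch of 600
#' phenotyped birds, duplicate pools of 10 per phenotype and sex (8 pools),
#' mean sequencing depth 66x, and a liability-threshold phenotype model
#' with the susceptible fraction fixed at \code{prevalence_target} by the
#' empirical liability quantile.
#'
#' @param n_individuals cohort size.
#' @param male_fraction fraction of males.
#' @param n_neutral_snps number of neutral (non-QTL) segregating SNPs.
#' @param chromosomes a \code{\link{chromosome_info}} layout.
#' @param density_gc_slope relative change in neutral SNP density per GC
#'   percentage point away from 47\% (the genome-wide mode); 0 for uniform.
#' @param qtls list of \code{\link{qtl_spec}}.
#' @param liability_sd standard deviation of the residual liability noise.
#' @param prevalence_target fraction of the cohort scored susceptible.
#' @param pool_size birds per pool.
#' @param n_replicates biological replicate pools per phenotype x sex cell.
#' @param mean_depth mean per-site per-pool sequencing depth (Poisson).
#' @param seq_error_rate symmetric per-read allele miscall rate.
#' @param seed RNG seed used by \code{\link{simulate_population}}.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 600L, male_fraction = 0.5,
                       n_neutral_snps = 2000L,
                       chromosomes = default_chromosomes(),
                       density_gc_slope = 0.04, qtls = list(),
                       liability_sd = 1, prevalence_target = 0.5,
                       pool_size = 10L, n_replicates = 2L, mean_depth = 66,
                       seq_error_rate = 0.002, seed = 1L) {
  stopifnot(prevalence_target > 0, prevalence_target < 1,
            male_fraction > 0, male_fraction < 1,
            inherits(chromosomes, "chromosome_info"),
            liability_sd >= 0, pool_size >= 1L, n_replicates >= 1L,
            mean_depth > 0, seq_error_rate >= 0, seq_error_rate < 0.5)
  if (length(qtls) && !all(vapply(qtls, inherits, TRUE, "qtl_spec")))
    stop_("qtls must be a list of qtl_spec objects")
  need <- pool_size * n_replicates * 4L
  if (need > n_individuals)
    stop_("pool demands infeasible: need ", need, " pooled birds but ",
          "cohort has ", n_individuals)
  structure(list(n_individuals = as.integer(n_individuals),
                 male_fraction = male_fraction,
                 n_neutral_snps = as.integer(n_neutral_snps),
                 chromosomes = chromosomes,
                 density_gc_slope = density_gc_slope, qtls = qtls,
                 liability_sd = liability_sd,
                 prevalence_target = prevalence_target,
                 pool_size = as.integer(pool_size),
                 n_replicates = as.integer(n_replicates),
                 mean_depth = mean_depth, seq_error_rate = seq_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Flatten qtls: partners become entries of their own; returns list of
# list(spec, is_partner, pair_id).
flatten_qtls <- function(qtls) {
  out <- list()
  for (i in seq_along(qtls)) {
    q <- qtls[[i]]
    out[[length(out) + 1L]] <- list(spec = q, pair = i, role = "main")
    if (!is.null(q$partner))
      out[[length(out) + 1L]] <- list(spec = q$partner, pair = i,
                                      role = "partner")
  }
  out
}

#' Simulate a phenotyped founder cohort
#'
#' Genotypes are drawn per site as Binomial(2, alt_freq) (Hardy-Weinberg
#' founders, sites independent except within perfectly linked QTL blocks).
#' Each bird's liability is the sum of its sex-specific QTL effects, any
#' epistatic dosage-product terms, and Gaussian noise; the susceptible
#' fraction is fixed at the configured prevalence by the empirical
#' liability quantile, so realized prevalence is exact per run.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{sim_population}: list with \code{sites}
#'   (incl. \code{qtl_id}), integer \code{genotypes} (sites x individuals,
#'   alt-allele dosage 0-2), \code{sex}, \code{phenotype}, \code{config}.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  chroms <- config$chromosomes
  n_male <- round(n * config$male_fraction)
  sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))

  # neutral sites: density scales with chromosome GC
  w <- chroms$length_bp *
    pmax(0.05, 1 + config$density_gc_slope * (chroms$gc_percent - 47))
  n_per <- as.vector(stats::rmultinom(1L, config$n_neutral_snps, w))
  neutral <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    if (n_per[i] == 0L) return(NULL)
    pos <- sort(sample.int(chroms$length_bp[i], n_per[i]))
    data.frame(chrom = chroms$name[i], pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(neutral))
    neutral <- data.frame(chrom = character(), pos = integer(),
                          stringsAsFactors = FALSE)
  neutral$alt_freq <- runif(nrow(neutral), 0.05, 0.95)
  neutral$qtl_id <- NA_integer_

  flat <- flatten_qtls(config$qtls)
  qtl_sites <- do.call(rbind, lapply(seq_along(flat), function(k) {
    q <- flat[[k]]$spec
    pos <- if (q$n_snps == 1L) q$pos
           else as.integer(round(seq(q$pos, q$pos + q$span_bp,
                                     length.out = q$n_snps)))
    data.frame(chrom = q$chrom, pos = unique(pos), alt_freq = q$alt_freq,
               qtl_id = k, stringsAsFactors = FALSE)
  }))
  sites <- rbind(neutral, qtl_sites)
  # QTL sites displace colliding neutral sites
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos),
                             fromLast = TRUE), , drop = FALSE]
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL

  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, nrow(sites), replace = TRUE)
  sites$alt <- vapply(sites$ref,
                      function(r) sample(setdiff(bases, r), 1L), "")

  geno <- matrix(0L, nrow = nrow(sites), ncol = n)
  neutral_idx <- which(is.na(sites$qtl_id))
  geno[neutral_idx, ] <- rbinom(length(neutral_idx) * n, 2L,
                                rep(sites$alt_freq[neutral_idx], n))
  # one causal dosage per QTL entry, copied to all linked sites
  causal <- lapply(seq_along(flat), function(k)
    rbinom(n, 2L, flat[[k]]$spec$alt_freq))
  for (k in seq_along(flat))
    geno[which(sites$qtl_id == k), ] <-
      matrix(causal[[k]], nrow = sum(sites$qtl_id == k, na.rm = TRUE),
             ncol = n, byrow = TRUE)

  liability <- rnorm(n, 0, config$liability_sd)
  is_male <- sex == "male"
  for (i in seq_along(config$qtls)) {
    q <- config$qtls[[i]]
    k_main <- which(vapply(flat, function(f)
      f$pair == i && f$role == "main", TRUE))
    d_main <- causal[[k_main]]
    beta <- ifelse(is_male, q$beta_male, q$beta_female)
    liability <- liability + beta * d_main
    if (!is.null(q$partner)) {
      k_p <- which(vapply(flat, function(f)
        f$pair == i && f$role == "partner", TRUE))
      d_p <- causal[[k_p]]
      p <- q$partner
      beta_p <- ifelse(is_male, p$beta_male, p$beta_female)
      gam <- ifelse(is_male, q$gamma, q$gamma_female)
      liability <- liability + beta_p * d_p + gam * d_main * d_p
    }
  }
  n_sus <- round(n * config$prevalence_target)
  sus <- rank(liability, ties.method = "first") > n - n_sus
  phenotype <- ifelse(sus, "susceptible", "resistant")

  structure(list(sites = sites, genotypes = geno, sex = sex,
                 phenotype = phenotype, liability = liability,
                 config = config),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(paste0("sim_population: %d individuals (%d male), %d SNP ",
                     "sites (%d QTL-linked), %.0f%% susceptible\n"),
              length(x$sex), sum(x$sex == "male"), nrow(x$sites),
              sum(!is.na(x$sites$qtl_id)),
              100 * mean(x$phenotype == "susceptible")))
  invisible(x)
}

#' Assign birds to sequencing pools
#'
#' Draws disjoint random pools of \code{pool_size} birds per
#' phenotype-by-sex cell and replicate, and computes each pool's true
#' allele frequency per site (mean dosage / 2; equal contribution per
#' bird).
#'
#' @param population a \code{\link{sim_population}}.
#' @param config a \code{\link{sim_config}}; defaults to the population's.
#' @return An object of class \code{pool_set}: list with \code{pools}
#'   (a \code{\link{pool_spec}}), \code{members} (list of individual
#'   indices per pool), and \code{freq} (sites x pools true frequencies).
#' @export
make_pools <- function(population, config = population$config) {
  stopifnot(inherits(population, "sim_population"))
  pools <- expand.grid(replicate = seq_len(config$n_replicates),
                       phenotype = PHENOTYPES, sex = SEXES,
                       stringsAsFactors = FALSE)
  pools$pool_id <- paste0(ifelse(pools$phenotype == "resistant", "R", "S"),
                          ifelse(pools$sex == "male", "M", "F"),
                          pools$replicate)
  spec <- pool_spec(pools$pool_id, pools$phenotype, pools$sex,
                    pools$replicate)
  members <- vector("list", nrow(spec))
  names(members) <- spec$pool_id
  for (cell in split(seq_len(nrow(spec)),
                     paste(spec$phenotype, spec$sex))) {
    ph <- spec$phenotype[cell[1L]]
    sx <- spec$sex[cell[1L]]
    avail <- which(population$phenotype == ph & population$sex == sx)
    need <- config$pool_size * length(cell)
    if (length(avail) < need)
      stop_(sprintf("cell %s %s has %d birds; %d needed for %d pool(s)",
                    ph, sx, length(avail), need, length(cell)))
    drawn <- sample(avail, need)
    for (j in seq_along(cell))
      members[[cell[j]]] <-
        drawn[((j - 1L) * config$pool_size + 1L):(j * config$pool_size)]
  }
  freq <- vapply(members, function(idx)
    rowMeans(population$genotypes[, idx, drop = FALSE]) / 2,
    numeric(nrow(population$sites)))
  freq <- matrix(freq, nrow = nrow(population$sites),
                 dimnames = list(NULL, spec$pool_id))
  structure(list(pools = spec, members = members, freq = freq,
                 sites = population$sites),
            class = "pool_set")
}

#' Sample sequencing reads over pools
#'
#' Per site and pool, depth is Poisson(\code{mean_depth}) and the observed
#' alt read count is Binomial(depth, f*), where
#' f* = f (1 - e) + (1 - f) e folds the symmetric sequencing error rate e
#' into the pool's true allele frequency f.
#'
#' @param pool_set a \code{\link{make_pools}} result (or a list with
#'   \code{freq}, \code{pools}, \code{sites}).
#' @param config a \code{\link{sim_config}} supplying \code{mean_depth} and
#'   \code{seq_error_rate}.
#' @return A \code{\link{pooled_snp_table}}.
#' @export
sample_reads <- function(pool_set, config) {
  f <- pool_set$freq
  stopifnot(all(f >= 0 & f <= 1))
  e <- config$seq_error_rate
  fstar <- f * (1 - e) + (1 - f) * e
  depth <- matrix(rpois(length(f), config$mean_depth), nrow = nrow(f))
  alt <- matrix(rbinom(length(f), as.vector(depth), as.vector(fstar)),
                nrow = nrow(f))
  pooled_snp_table(pool_set$sites[, c("chrom", "pos", "ref", "alt")],
                   pool_set$pools, alt, depth)
}

#' Realized QTL truth table
#'
#' For each configured QTL entry (epistatic partners included), the
#' realized Res-Sus allele-frequency difference per sex among the pooled
#' birds (replicate-averaged true pool frequencies), and the true block
#' interval. This is the yardstick the read-sampling error bound applies
#' to.
#'
#' @param population a \code{\link{sim_population}}.
#' @param pool_set the matching \code{\link{make_pools}} result.
#' @return A data frame of class \code{truth_table}: qtl_id, locus role,
#'   chrom, start_bp, stop_bp, d_male, d_female.
#' @export
truth_table <- function(population, pool_set) {
  flat <- flatten_qtls(population$config$qtls)
  if (!length(flat))
    return(structure(data.frame(), class = c("truth_table", "data.frame")))
  spec <- pool_set$pools
  grp_freq <- function(site_row, ph, sx) {
    cols <- spec$pool_id[spec$phenotype == ph & spec$sex == sx]
    mean(pool_set$freq[site_row, cols])
  }
  rows <- lapply(seq_along(flat), function(k) {
    q <- flat[[k]]$spec
    site_row <- which(population$sites$qtl_id == k)[1L]
    data.frame(qtl_id = k, pair = flat[[k]]$pair, role = flat[[k]]$role,
               chrom = q$chrom, start_bp = q$pos,
               stop_bp = q$pos + q$span_bp,
               d_male = grp_freq(site_row, "resistant", "male") -
                 grp_freq(site_row, "susceptible", "male"),
               d_female = grp_freq(site_row, "resistant", "female") -
                 grp_freq(site_row, "susceptible", "female"),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("truth_table", "data.frame"))
}

#' Run the full generator
#'
#' Seeds the RNG once (from the configuration) and runs population
#' simulation, pool assignment, and read sampling; identical configurations
#' give bit-identical output.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{population}, \code{pools} (a \code{pool_set}),
#'   \code{counts} (a \code{\link{pooled_snp_table}}), and \code{truth}
#'   (a \code{\link{truth_table}}).
#' @examples
#' sim <- simulate_poolseq(sim_config(n_individuals = 160,
#'                                    n_neutral_snps = 50, seed = 7))
#' sim$counts
#' @export
simulate_poolseq <- function(config) {
  population <- simulate_population(config)
  pools <- make_pools(population, config)
  counts <- sample_reads(pools, config)
  list(population = population, pools = pools, counts = counts,
       truth = truth_table(population, pools))
}
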