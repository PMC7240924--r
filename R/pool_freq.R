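#' Per-pool allele frequency
#'
#' The pool-seq frequency estimate: alt reads over total depth. Zero-depth
#' cells give NaN rather than an error, so masked sites propagate.
#'
#' @param alt_count,depth non-negative integer vectors (recycled), with
#'   \code{alt_count <= depth}.
#' @return Numeric vector of frequencies in [0, 1], NaN where depth is 0.
#' @examples
#' pool_frequency(33, 66)
#' @export
pool_frequency <- function(alt_count, depth) {
  if (any(alt_count < 0) || any(depth < 0))
    stop_("counts must be non-negative")
  if (any(alt_count > depth & depth > 0))
    stop_("alt_count exceeds depth")
  out <- alt_count / depth
  out[depth == 0] <- NaN
  out
}

#' Replicate-averaged group frequencies
#'
#' Averages per-pool allele frequencies over biological replicates within
#' each phenotype-by-sex group, the replicate-combination step of the scan.
#' The mean is unweighted across replicates; replicate pools with depth
#' below \code{min_depth} at a site are excluded there, and a group with no
#' passing replicate is masked (NaN).
#'
#' @param x a \code{\link{pooled_snp_table}}.
#' @param min_depth minimum per-pool depth for a replicate to contribute at
#'   a site (the high-quality-SNP proxy; default 10).
#' @return An object of class \code{freq_track}: list with \code{sites},
#'   \code{groups} (phenotype, sex), \code{freq} (sites x groups),
#'   \code{depth} (summed contributing replicate depths per group).
#' @export
group_frequencies <- function(x, min_depth = 10L) {
  stopifnot(inherits(x, "pooled_snp_table"))
  groups <- unique(x$pools[, c("phenotype", "sex")])
  rownames(groups) <- NULL
  if (nrow(groups) == 0L) stop_("no pools, no groups")
  gid <- paste(groups$phenotype, groups$sex, sep = "_")
  pf <- pool_frequency(x$alt_count, x$depth)
  pf[x$depth < min_depth] <- NA_real_
  d_eff <- x$depth
  d_eff[x$depth < min_depth] <- 0L
  freq <- matrix(NA_real_, nrow(x$sites), nrow(groups),
                 dimnames = list(NULL, gid))
  dsum <- matrix(0L, nrow(x$sites), nrow(groups),
                 dimnames = list(NULL, gid))
  for (g in seq_len(nrow(groups))) {
    cols <- which(x$pools$phenotype == groups$phenotype[g] &
                    x$pools$sex == groups$sex[g])
    freq[, g] <- rowMeans(pf[, cols, drop = FALSE], na.rm = TRUE)
    dsum[, g] <- rowSums(d_eff[, cols, drop = FALSE])
  }
  freq[is.nan(freq)] <- NaN  # rowMeans over all-NA yields NaN already
  structure(list(sites = x$sites, groups = groups, freq = freq,
                 depth = dsum, min_depth = min_depth),
            class = "freq_track")
}

#' @export
print.freq_track <- function(x, ...) {
  cat(sprintf("freq_track: %d sites x %d phenotype/sex groups (%s)\n",
              nrow(x$sites), nrow(x$groups),
              paste(colnames(x$freq), collapse = ", ")))
  invisible(x)
}

#' Res-Sus frequency-difference track
#'
#' The scan statistic: per site and sex, the replicate-averaged
#' non-reference allele frequency in resistant pools minus that in
#' susceptible pools. Positive values mean the non-reference allele tracks
#' resistance. NaN group frequencies propagate.
#'
#' @param freqs a \code{\link{group_frequencies}} result.
#' @return A data frame of class \code{diff_track} with columns
#'   \code{chrom}, \code{pos}, and \code{d_male} / \code{d_female} for each
#'   sex with both phenotypes present; group summed depths are carried in
#'   attribute \code{depth} for standard-error computations.
#' @export
diff_track <- function(freqs) {
  stopifnot(inherits(freqs, "freq_track"))
  out <- freqs$sites[, c("chrom", "pos")]
  depths <- list()
  for (s in SEXES) {
    rcol <- paste("resistant", s, sep = "_")
    scol <- paste("susceptible", s, sep = "_")
    if (!all(c(rcol, scol) %in% colnames(freqs$freq))) next
    out[[paste0("d_", s)]] <- freqs$freq[, rcol] - freqs$freq[, scol]
    depths[[s]] <- list(resistant = freqs$depth[, rcol],
                        susceptible = freqs$depth[, scol])
  }
  if (!length(depths))
    stop_("no sex has both phenotypes; cannot difference")
  structure(out, depth = depths, class = c("diff_track", "data.frame"))
}

track_sexes <- function(track) {
  sub("^d_", "", grep("^d_", names(track), value = TRUE))
}

#' Per-chromosome SNP density
#'
#' SNP density per 100 bp per chromosome (presence-based: pool count and
#' depth do not enter), with GC pairings for the density-by-GC scatter and
#' the across-chromosome mean and standard deviation.
#'
#' @param x a \code{\link{pooled_snp_table}} (or any data frame of sites
#'   with a \code{chrom} column).
#' @param chrom_info a \code{\link{chromosome_info}} covering the
#'   chromosomes of interest; chromosomes without SNPs get density 0.
#' @return A data frame with columns chrom, n_snps, length_bp, gc_percent,
#'   snp_per_100bp, plus attributes \code{mean_density} and
#'   \code{sd_density}.
#' @examples
#' ci <- chromosome_info("chr", 1e5, 45)
#' @export
snp_density <- function(x, chrom_info) {
  stopifnot(inherits(chrom_info, "chromosome_info"))
  sites <- if (inherits(x, "pooled_snp_table")) x$sites else x
  counts <- table(factor(sites$chrom, levels = chrom_info$name))
  out <- data.frame(chrom = chrom_info$name,
                    n_snps = as.integer(counts),
                    length_bp = chrom_info$length_bp,
                    gc_percent = chrom_info$gc_percent,
                    stringsAsFactors = FALSE)
  out$snp_per_100bp <- 100 * out$n_snps / out$length_bp
  structure(out, mean_density = mean(out$snp_per_100bp),
            sd_density = stats::sd(out$snp_per_100bp))
}
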