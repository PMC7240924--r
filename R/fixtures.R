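#' Load a packaged summary-table fixture
#'
#' The package ships the published summary tables of the ascites pool-seq
#' study as plain-text fixtures: the 28 candidate QTL regions with per-sex
#' peak Res-Sus frequency differentials and gene lists
#' (\code{"table1_regions"}), the single-locus LRRTM4 genotype-by-phenotype
#' summary (\code{"table2_lrrtm4"}), and the two-locus LRRTM4 x CPQ
#' combined-genotype summary (\code{"table3_combined"}).
#'
#' For the genotype tables, phenotype counts per class are reconstructed
#' from the published class sizes and percentages as
#' \code{round(n * pct / 100)} (halves away from zero); they can differ from
#' the unpublished archived counts by one. The published adjusted P-values
#' are carried verbatim in \code{p_adj_printed} (Excel-style, so values
#' above 1 occur).
#'
#' Structural invariants are asserted at load: the region table has exactly
#' 28 rows on exactly 13 distinct chromosomes, and every genotype row's
#' percentages sum to 100 within printed rounding (99.8-100.2).
#'
#' @param name one of \code{"table1_regions"}, \code{"table2_lrrtm4"},
#'   \code{"table3_combined"}.
#' @return A data frame. Region tables have columns chrom, start_mbp,
#'   stop_mbp, size_mbp, male_diff_pct, female_diff_pct, genes. Genotype
#'   tables have subset, genotype (composite label; for the two-locus table
#'   also the per-locus labels), n, pct_sus, pct_res, obs_sus, obs_res,
#'   p_adj_printed.
#' @examples
#' regions <- load_fixture("table1_regions")
#' summarize_regions(classify_regions(regions))
#' @export
load_fixture <- function(name = c("table1_regions", "table2_lrrtm4",
                                  "table3_combined")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "poolqtl",
                      mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (name == "table1_regions") {
    df$chrom <- as.character(df$chrom)
    stopifnot(nrow(df) == 28L, length(unique(df$chrom)) == 13L,
              all(abs(df$male_diff_pct) <= 100),
              all(abs(df$female_diff_pct) <= 100),
              all(df$start_mbp <= df$stop_mbp))
    df$start_bp <- as.integer(round(df$start_mbp * 1e6))
    df$stop_bp <- as.integer(round(df$stop_mbp * 1e6))
  } else {
    if (name == "table3_combined") df$genotype <- paste0(df$lrrtm4, df$cpq)
    psum <- df$pct_sus + df$pct_res
    stopifnot(all(psum >= 99.8 & psum <= 100.2))
    df$obs_sus <- as.integer(round_half_up(df$n * df$pct_sus / 100))
    df$obs_res <- as.integer(round_half_up(df$n * df$pct_res / 100))
    stopifnot(all(abs(df$obs_sus + df$obs_res - df$n) <= 1L))
  }
  df
}
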