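#' Call candidate QTL regions from a difference track
#'
#' A deterministic formalization of the visual IGV cluster scan: per sex, a
#' seed cluster is a maximal run of SNPs whose Res-Sus frequency difference
#' has magnitude at or above \code{threshold} (inclusive) with a common
#' sign, consecutive members at most \code{max_gap_bp} apart. Clusters with
#' at least \code{min_snps} members become regions; regions from either sex
#' on the same chromosome whose intervals come within \code{merge_bp} are
#' merged, retaining per-sex supporting-SNP counts and signed peak
#' differentials. A sex without a supporting cluster in a merged region
#' reports a peak of 0, the convention of the published region table.
#'
#' @param diffs a \code{\link{diff_track}}, sorted by (chrom, pos).
#' @param threshold cluster membership threshold on |d|, in (0, 1].
#' @param min_snps minimum SNPs per cluster.
#' @param max_gap_bp maximum bp between consecutive cluster members.
#' @param merge_bp merge distance between called intervals.
#' @return A data frame of class \code{candidate_regions}: chrom, start_bp,
#'   stop_bp, size_mbp, n_snps_male, n_snps_female, peak_diff_male,
#'   peak_diff_female, male_diff_pct, female_diff_pct; sorted by
#'   (chrom, start).
#' @export
call_regions <- function(diffs, threshold = 0.20, min_snps = 10L,
                         max_gap_bp = 20000L, merge_bp = 50000L) {
  stopifnot(inherits(diffs, "diff_track"))
  if (!(threshold > 0 && threshold <= 1))
    stop_("threshold must be in (0, 1]")
  sexes <- track_sexes(diffs)
  clusters <- do.call(rbind, lapply(sexes, function(s)
    find_clusters(diffs, s, threshold, min_snps, max_gap_bp)))
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      stop_bp = integer(), size_mbp = numeric(),
                      n_snps_male = integer(), n_snps_female = integer(),
                      peak_diff_male = numeric(),
                      peak_diff_female = numeric(),
                      male_diff_pct = numeric(), female_diff_pct = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(clusters) || nrow(clusters) == 0L)
    return(structure(empty, class = c("candidate_regions", "data.frame")))
  clusters <- clusters[order(clusters$chrom, clusters$start_bp), ,
                       drop = FALSE]
  merged_id <- integer(nrow(clusters))
  cur <- 0L
  cur_chrom <- ""
  cur_stop <- -Inf
  for (i in seq_len(nrow(clusters))) {
    if (clusters$chrom[i] != cur_chrom ||
        clusters$start_bp[i] > cur_stop + merge_bp) {
      cur <- cur + 1L
      cur_chrom <- clusters$chrom[i]
      cur_stop <- clusters$stop_bp[i]
    } else cur_stop <- max(cur_stop, clusters$stop_bp[i])
    merged_id[i] <- cur
  }
  rows <- lapply(split(seq_len(nrow(clusters)), merged_id), function(idx) {
    cl <- clusters[idx, , drop = FALSE]
    out <- data.frame(chrom = cl$chrom[1L], start_bp = min(cl$start_bp),
                      stop_bp = max(cl$stop_bp), stringsAsFactors = FALSE)
    out$size_mbp <- (out$stop_bp - out$start_bp) / 1e6
    for (s in SEXES) {
      cs <- cl[cl$sex == s, , drop = FALSE]
      out[[paste0("n_snps_", s)]] <- sum(cs$n_snps)
      out[[paste0("peak_diff_", s)]] <-
        if (nrow(cs)) cs$peak[which.max(abs(cs$peak))] else 0
    }
    out
  })
  regions <- do.call(rbind, rows)
  regions$male_diff_pct <- round_half_up(100 * regions$peak_diff_male)
  regions$female_diff_pct <- round_half_up(100 * regions$peak_diff_female)
  regions <- regions[order(regions$chrom, regions$start_bp), , drop = FALSE]
  rownames(regions) <- NULL
  structure(regions, class = c("candidate_regions", "data.frame"))
}

# Seed clusters for one sex: maximal same-sign runs of |d| >= threshold
# with bounded gaps, >= min_snps members.
find_clusters <- function(diffs, sex, threshold, min_snps, max_gap_bp) {
  d <- diffs[[paste0("d_", sex)]]
  keep <- is.finite(d) & abs(d) >= threshold
  if (!any(keep)) return(NULL)
  sub <- data.frame(chrom = diffs$chrom[keep], pos = diffs$pos[keep],
                    d = d[keep], stringsAsFactors = FALSE)
  new_run <- c(TRUE, sub$chrom[-1L] != sub$chrom[-nrow(sub)] |
                 diff(sub$pos) > max_gap_bp |
                 sign(sub$d[-1L]) != sign(sub$d[-nrow(sub)]))
  run_id <- cumsum(new_run)
  rows <- lapply(split(seq_len(nrow(sub)), run_id), function(idx) {
    if (length(idx) < min_snps) return(NULL)
    dd <- sub$d[idx]
    data.frame(chrom = sub$chrom[idx[1L]], start_bp = min(sub$pos[idx]),
               stop_bp = max(sub$pos[idx]), sex = sex,
               n_snps = length(idx), peak = dd[which.max(abs(dd))],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify regions by sex pattern and direction
#'
#' A sex is "associated" with a region when the magnitude of its peak
#' Res-Sus differential reaches the association threshold (inclusive, so a
#' printed 20\% counts). Direction follows the signs: positive means the
#' non-reference allele tracks resistance, negative susceptibility. A
#' region associated in neither sex is not a region and raises an error.
#'
#' @param male_diff_pct,female_diff_pct signed percent differentials in
#'   [-100, 100] (vectors of equal length).
#' @param assoc_threshold_pct association threshold in percent (default 20).
#' @return A data frame with columns \code{sex_pattern} (\code{both},
#'   \code{male_only}, \code{female_only}) and \code{direction} (one of
#'   \code{res_both}, \code{sus_both}, \code{res_male_only},
#'   \code{sus_male_only}, \code{res_female_only}, \code{sus_female_only},
#'   \code{res_male_sus_female}, \code{sus_male_res_female}).
#' @examples
#' classify_region(40, 20)    # resistance-associated in both sexes
#' classify_region(45, -25)   # opposite directions
#' @export
classify_region <- function(male_diff_pct, female_diff_pct,
                            assoc_threshold_pct = 20) {
  m <- as.numeric(male_diff_pct)
  f <- as.numeric(female_diff_pct)
  stopifnot(length(m) == length(f))
  if (any(abs(m) > 100 | abs(f) > 100, na.rm = TRUE))
    stop_("differentials must be percentages in [-100, 100]")
  m_as <- abs(m) >= assoc_threshold_pct
  f_as <- abs(f) >= assoc_threshold_pct
  if (any(!m_as & !f_as))
    stop_("region(s) associated in neither sex at row(s) ",
          paste(which(!m_as & !f_as), collapse = ", "))
  dir_word <- function(x) ifelse(x > 0, "res", "sus")
  sex_pattern <- ifelse(m_as & f_as, "both",
                        ifelse(m_as, "male_only", "female_only"))
  direction <- ifelse(
    m_as & f_as,
    ifelse(sign(m) == sign(f), paste0(dir_word(m), "_both"),
           paste0(dir_word(m), "_male_", dir_word(f), "_female")),
    ifelse(m_as, paste0(dir_word(m), "_male_only"),
           paste0(dir_word(f), "_female_only")))
  data.frame(sex_pattern = sex_pattern, direction = direction,
             stringsAsFactors = FALSE)
}

#' @rdname classify_region
#' @param regions a data frame with \code{male_diff_pct} and
#'   \code{female_diff_pct} columns (called regions or the packaged region
#'   fixture); classification columns are appended.
#' @export
classify_regions <- function(regions, assoc_threshold_pct = 20) {
  cls <- classify_region(regions$male_diff_pct, regions$female_diff_pct,
                         assoc_threshold_pct)
  regions$sex_pattern <- cls$sex_pattern
  regions$direction <- cls$direction
  regions
}

#' Summarize classified regions
#'
#' Region counts overall, per chromosome, per sex pattern, and per
#' direction, with any gene annotations carried through unchanged.
#'
#' @param regions a classified region table (see
#'   \code{\link{classify_regions}}; unclassified tables are classified
#'   with the default threshold first).
#' @return A list of class \code{region_summary}: \code{n_regions},
#'   \code{n_chromosomes}, \code{sex_pattern} (named count vector over the
#'   3 patterns), \code{direction} (named count vector over the 8
#'   directions), and \code{genes} (if present in the input).
#' @export
summarize_regions <- function(regions) {
  if (nrow(regions) == 0L) stop_("no regions to summarize")
  if (is.null(regions$sex_pattern)) regions <- classify_regions(regions)
  patterns <- c("both", "male_only", "female_only")
  directions <- c("res_both", "sus_both", "res_male_only", "sus_male_only",
                  "res_female_only", "sus_female_only",
                  "res_male_sus_female", "sus_male_res_female")
  out <- list(
    n_regions = nrow(regions),
    n_chromosomes = length(unique(regions$chrom)),
    sex_pattern = table(factor(regions$sex_pattern, levels = patterns)),
    direction = table(factor(regions$direction, levels = directions)))
  out$sex_pattern <- setNames(as.integer(out$sex_pattern), patterns)
  out$direction <- setNames(as.integer(out$direction), directions)
  if (!is.null(regions$genes)) out$genes <- regions$genes
  class(out) <- "region_summary"
  out
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("%d candidate region(s) on %d chromosome(s)\n",
              x$n_regions, x$n_chromosomes))
  cat("  sex pattern: ",
      paste(sprintf("%s=%d", names(x$sex_pattern), x$sex_pattern),
            collapse = ", "), "\n", sep = "")
  cat("  direction:   ",
      paste(sprintf("%s=%d", names(x$direction), x$direction),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
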