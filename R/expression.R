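#' Relative expression by the delta-delta-Ct method
#'
#' Computes per-group relative expression from RT-qPCR quantification
#' cycles against a reference gene (here conventionally TBP). Technical
#' replicates are averaged per sample first; each sample's
#' delta-Ct = ct_target - ct_reference, and a group's delta-delta-Ct is the
#' mean (with sd) over its samples, with fold change 2^(-ddCt) relative to
#' the reference gene. With no calibrator sample the delta-delta-Ct equals
#' the delta-Ct, the convention used here.
#'
#' Records whose target Ct is missing or above \code{max_cycles} are
#' treated as "not detected"; a group with no detected record is reported
#' with \code{detected = FALSE} and no fold change.
#'
#' @param records data frame with columns \code{sample_id},
#'   \code{ct_target}, \code{ct_reference}, and the grouping column
#'   (plus optionally \code{tissue}, \code{gene}).
#' @param group_by name of the grouping column (default
#'   \code{"genotype"}).
#' @param max_cycles detection cutoff on the target Ct (default 25, the
#'   cycle budget of the assay).
#' @return A data frame: group, n_samples, detected, ddct_mean, ddct_sd,
#'   fold_change.
#' @examples
#' fold_change(6)   # 0.015625: ~0.016 of reference-gene expression
#' @export
delta_delta_ct <- function(records, group_by = "genotype",
                           max_cycles = 25) {
  need <- c("sample_id", "ct_target", "ct_reference", group_by)
  if (!all(need %in% names(records)))
    stop_("records needs columns: ", paste(need, collapse = ", "))
  if (any(records$ct_reference <= 0, na.rm = TRUE) ||
      any(records$ct_target <= 0, na.rm = TRUE))
    stop_("Ct values must be positive")
  records$detected <- !is.na(records$ct_target) &
    records$ct_target <= max_cycles
  rows <- lapply(split(records, records[[group_by]]), function(g) {
    det <- g[g$detected, , drop = FALSE]
    if (nrow(det) == 0L)
      return(data.frame(group = g[[group_by]][1L],
                        n_samples = 0L, detected = FALSE,
                        ddct_mean = NA_real_, ddct_sd = NA_real_,
                        fold_change = NA_real_, stringsAsFactors = FALSE))
    # technical replicates: average Ct per sample before differencing
    tgt <- tapply(det$ct_target, det$sample_id, mean)
    ref <- tapply(det$ct_reference, det$sample_id, mean)
    dct <- tgt - ref[names(tgt)]
    data.frame(group = g[[group_by]][1L], n_samples = length(dct),
               detected = TRUE, ddct_mean = mean(dct),
               ddct_sd = if (length(dct) > 1L) stats::sd(dct) else NA_real_,
               fold_change = fold_change(mean(dct)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname delta_delta_ct
#' @param ddct delta-delta-Ct value(s).
#' @export
fold_change <- function(ddct) 2^(-ddct)

#' Compare expression between two genotype groups
#'
#' Unequal-variance (Welch) two-sample t-test on per-sample delta-Ct
#' values, one-tailed by default (the spreadsheet "one way with unequal
#' variance" convention: the one-tailed P is half the two-tailed P of the
#' absolute t, so identical groups give exactly 0.5).
#'
#' @param group_a,group_b numeric vectors of per-sample delta-Ct values
#'   (each of length >= 2).
#' @param tails 1 (default) or 2.
#' @return A list: \code{t}, \code{df} (Welch-Satterthwaite), \code{p}.
#' @export
compare_alleles <- function(group_a, group_b, tails = 1L) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_("each group needs at least 2 values")
  if (!tails %in% c(1L, 2L)) stop_("tails must be 1 or 2")
  na <- length(group_a)
  nb <- length(group_b)
  va <- stats::var(group_a) / na
  vb <- stats::var(group_b) / nb
  if (va + vb == 0)
    stop_("zero variance in both groups; t undefined")
  t_stat <- (mean(group_a) - mean(group_b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p_two <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = if (tails == 1L) p_two / 2 else p_two)
}
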