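#' Expected phenotype counts per genotype class
#'
#' Expected counts are computed from the observed genotype-class sizes and
#' the overall phenotype rate of the subset: for class g of size n_g,
#' exp_sus(g) = n_g * total_sus / total (and analogously for resistant).
#' Individuals of unknown sex contribute to \code{"all"} only.
#'
#' @param x a \code{\link{genotype_table}}.
#' @param subset \code{"all"}, \code{"male"}, or \code{"female"}.
#' @return A data frame: class, n, obs_sus, obs_res, exp_sus, exp_res.
#' @export
expected_counts <- function(x, subset = c("all", "male", "female")) {
  subset <- match.arg(subset)
  counts <- class_counts(x, subset)
  expected_from_counts(counts)
}

class_counts <- function(x, subset) {
  stopifnot(inherits(x, "genotype_table"))
  keep <- if (subset == "all") rep(TRUE, nrow(x)) else x$sex == subset
  sub <- x[keep, , drop = FALSE]
  lab <- composite_label(sub)
  ok <- !is.na(lab)
  sub <- sub[ok, , drop = FALSE]
  lab <- lab[ok]
  if (nrow(sub) == 0L) stop_("subset '", subset, "' is empty")
  sus <- sub$phenotype == "susceptible"
  cls <- sort(unique(lab))
  lab <- factor(lab, levels = cls)
  data.frame(class = cls,
             obs_sus = as.integer(tapply(sus, lab, sum, default = 0L)),
             obs_res = as.integer(tapply(!sus, lab, sum, default = 0L)),
             stringsAsFactors = FALSE)
}

expected_from_counts <- function(counts) {
  n <- counts$obs_sus + counts$obs_res
  total <- sum(n)
  if (total == 0L) stop_("no individuals in subset")
  rate_sus <- sum(counts$obs_sus) / total
  data.frame(class = counts$class, n = n,
             obs_sus = counts$obs_sus, obs_res = counts$obs_res,
             exp_sus = n * rate_sus, exp_res = n * (1 - rate_sus),
             stringsAsFactors = FALSE)
}

#' Two-cell chi-square of observed versus expected counts
#'
#' The spreadsheet-semantics goodness-of-fit test used on each genotype
#' class: chi2 = sum (obs - exp)^2 / exp over the susceptible and resistant
#' cells, with the upper-tail P at df = 1 (a 1-row, 2-column CHITEST
#' range). Non-positive expected cells give NaN with a warning.
#'
#' @param obs,exp numeric length-2 vectors (susceptible, resistant).
#' @return Named numeric vector \code{c(chi2, p)}.
#' @examples
#' chi2_obs_vs_exp(c(112, 134), c(88.4, 157.6))
#' @export
chi2_obs_vs_exp <- function(obs, exp) {
  stopifnot(length(obs) == 2L, length(exp) == 2L)
  if (any(exp <= 0)) {
    warning("non-positive expected count; class untested", call. = FALSE)
    return(c(chi2 = NaN, p = NaN))
  }
  chi2 <- sum((obs - exp)^2 / exp)
  c(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Genotype-phenotype association with Bonferroni adjustment
#'
#' For each subset (all/male/female) and genotype class, tests observed
#' phenotype counts against expectations from the subset's overall
#' phenotype rate with the two-cell chi-square, then applies a simple
#' Bonferroni adjustment: raw P times the number of tested classes in that
#' subset, capped at 1. Classes whose frequency in the subset does not
#' exceed \code{min_class_freq} are reported untested (no P), and do not
#' count toward the multiplier.
#'
#' @param x a \code{\link{genotype_table}} (one locus gives up to 3
#'   classes; two loci give up to 9 combined classes).
#' @param min_class_freq class-frequency filter (default 0.10: only
#'   classes above 10\% are tested).
#' @param alpha significance level on the adjusted P (default 0.05).
#' @param subsets which subsets to analyse.
#' @return A data frame of class \code{assoc_result}: subset, class, n,
#'   obs_sus, obs_res, exp_sus, exp_res, freq, tested, chi2, p_raw, p_adj,
#'   significant.
#' @seealso \code{\link{associate_counts}} for pre-tabulated counts.
#' @export
associate <- function(x, min_class_freq = 0.10, alpha = 0.05,
                      subsets = c("all", "male", "female")) {
  counts <- do.call(rbind, lapply(subsets, function(s) {
    cc <- class_counts(x, s)
    cc$subset <- s
    cc
  }))
  associate_counts(counts, min_class_freq = min_class_freq, alpha = alpha)
}

#' @rdname associate
#' @param counts a data frame with columns \code{subset}, \code{class},
#'   \code{obs_sus}, \code{obs_res} (e.g. a reconstructed published table;
#'   see \code{\link{load_fixture}}, whose \code{genotype} column is
#'   accepted as \code{class}).
#' @export
associate_counts <- function(counts, min_class_freq = 0.10, alpha = 0.05) {
  if (is.null(counts$class) && !is.null(counts$genotype))
    counts$class <- counts$genotype
  need <- c("subset", "class", "obs_sus", "obs_res")
  if (!all(need %in% names(counts)))
    stop_("counts needs columns: ", paste(need, collapse = ", "))
  rows <- lapply(split(counts, counts$subset), function(cc) {
    if (length(unique(cc$class)) < 2L)
      stop_("subset '", cc$subset[1L], "' has fewer than 2 genotype classes")
    df <- expected_from_counts(cc)
    df$subset <- cc$subset[1L]
    df$freq <- df$n / sum(df$n)
    df$tested <- df$freq > min_class_freq & df$exp_sus > 0 & df$exp_res > 0
    stat <- t(vapply(seq_len(nrow(df)), function(i) {
      if (!df$tested[i]) return(c(chi2 = NA_real_, p = NA_real_))
      chi2_obs_vs_exp(c(df$obs_sus[i], df$obs_res[i]),
                      c(df$exp_sus[i], df$exp_res[i]))
    }, c(chi2 = 0, p = 0)))
    df$chi2 <- stat[, "chi2"]
    df$p_raw <- stat[, "p"]
    k <- sum(df$tested)
    df$p_adj <- pmin(1, df$p_raw * k)
    df$significant <- df$tested & !is.na(df$p_adj) & df$p_adj < alpha
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("subset", "class", "n", "obs_sus", "obs_res", "exp_sus",
                 "exp_res", "freq", "tested", "chi2", "p_raw", "p_adj",
                 "significant")]
  structure(out, class = c("assoc_result", "data.frame"))
}

#' Hardy-Weinberg agreement check
#'
#' Estimates the non-reference allele frequency from genotype counts,
#' forms the Hardy-Weinberg expected genotype frequencies (q^2, 2pq, p^2
#' for hom_ref/het/hom_alt with p the non-reference frequency), and runs a
#' df = 1 goodness-of-fit chi-square of observed versus expected counts.
#' Monomorphic samples are degenerate and return chi2 = 0, p = 1.
#'
#' @param x a \code{\link{genotype_table}} (first locus used unless
#'   \code{locus} names one) or a named count vector with elements
#'   \code{hom_ref}, \code{het}, \code{hom_alt}.
#' @param locus locus name when \code{x} is a two-locus table.
#' @return A list of class \code{hwe_report}: n, allele_freq (non-ref),
#'   observed and expected genotype frequency vectors, expected counts,
#'   chi2, p.
#' @export
hwe_check <- function(x, locus = NULL) {
  if (inherits(x, "genotype_table")) {
    locus <- locus %||% attr(x, "loci")[1L]
    st <- genotype_state(x[[locus]], attr(x, "code_maps")[[locus]])
    counts <- table(factor(st, levels = GT_STATES))
    counts <- setNames(as.integer(counts), GT_STATES)
  } else {
    if (!all(GT_STATES %in% names(x)))
      stop_("counts must be named hom_ref, het, hom_alt")
    counts <- setNames(as.integer(x[GT_STATES]), GT_STATES)
  }
  n <- sum(counts)
  if (n < 1L) stop_("no individuals")
  p <- (2 * counts[["hom_alt"]] + counts[["het"]]) / (2 * n)
  q <- 1 - p
  exp_freq <- c(hom_ref = q^2, het = 2 * p * q, hom_alt = p^2)
  obs_freq <- counts / n
  exp_n <- exp_freq * n
  if (p == 0 || p == 1) {
    chi2 <- 0
  } else {
    chi2 <- sum((counts - exp_n)^2 / exp_n)
  }
  structure(list(n = n, allele_freq = p, observed = obs_freq,
                 expected = exp_freq, expected_counts = exp_n, chi2 = chi2,
                 p = pchisq(chi2, df = 1L, lower.tail = FALSE)),
            class = "hwe_report")
}

#' @export
print.hwe_report <- function(x, ...) {
  cat(sprintf("HWE check: n=%d, non-ref allele freq=%.3f, chi2=%.3f, p=%.3g\n",
              x$n, x$allele_freq, x$chi2, x$p))
  invisible(x)
}

#' Combine two single-locus genotype tables
#'
#' Joins two genotype tables on sample id to form the 9-class combined
#' genotype table of a two-locus epistasis screen; composite classes are
#' labelled by concatenated per-locus labels (e.g. \code{"RRCC"}). Samples
#' missing either locus are dropped with a message giving the count; sex
#' and phenotype are taken from the first table (a mismatch warns).
#'
#' @param table_a,table_b single-locus \code{\link{genotype_table}}s with
#'   distinct locus names.
#' @return A two-locus \code{\link{genotype_table}}.
#' @export
combine_genotypes <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "genotype_table"),
            inherits(table_b, "genotype_table"))
  la <- attr(table_a, "loci")
  lb <- attr(table_b, "loci")
  if (length(la) != 1L || length(lb) != 1L || la == lb)
    stop_("need two single-locus tables with distinct loci")
  common <- intersect(table_a$sample_id, table_b$sample_id)
  dropped <- length(unique(c(table_a$sample_id, table_b$sample_id))) -
    length(common)
  if (!length(common)) {
    warning("no shared samples between tables", call. = FALSE)
  } else if (dropped > 0L) {
    message(dropped, " sample(s) missing one locus; dropped")
  }
  a <- table_a[match(common, table_a$sample_id), , drop = FALSE]
  b <- table_b[match(common, table_b$sample_id), , drop = FALSE]
  if (length(common) &&
      (any(a$phenotype != b$phenotype) ||
       any(a$sex != b$sex & b$sex != "unknown" & a$sex != "unknown")))
    warning("sex/phenotype mismatch between tables; using first table's",
            call. = FALSE)
  df <- data.frame(sample_id = common, sex = a$sex,
                   phenotype = a$phenotype, stringsAsFactors = FALSE)
  df[[la]] <- a[[la]]
  df[[lb]] <- b[[lb]]
  genotype_table(df, c(la, lb),
                 code_maps = c(attr(table_a, "code_maps"),
                               attr(table_b, "code_maps")))
}

#' Odds of resistance
#'
#' @param obs_res,obs_sus resistant and susceptible counts in a genotype
#'   class (\code{obs_sus} must be positive).
#' @return A list: \code{odds} (res/sus) and \code{label}, the
#'   nearest-integer "r:1" rendering.
#' @examples
#' odds_of_resistance(52, 9)  # ~5.8, "6:1"
#' @export
odds_of_resistance <- function(obs_res, obs_sus) {
  stopifnot(length(obs_res) == 1L, length(obs_sus) == 1L, obs_res >= 0)
  if (obs_sus <= 0) stop_("obs_sus must be positive")
  odds <- obs_res / obs_sus
  list(odds = odds, label = sprintf("%d:1", as.integer(round_half_up(odds))))
}
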