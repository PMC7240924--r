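#' Pool metadata table
#'
#' Describes the sequencing pools of a pool-seq experiment: each pool is a
#' DNA mix of equal contributions from \code{pool_size} birds sharing one
#' phenotype and one sex, with biological replicate pools numbered from 1.
#'
#' @param pool_id character vector of unique short pool identifiers.
#' @param phenotype \code{"resistant"} or \code{"susceptible"}, per pool.
#' @param sex \code{"male"} or \code{"female"}, per pool.
#' @param replicate integer replicate number (>= 1), per pool.
#' @return A data frame of class \code{pool_spec} with one row per pool.
#' @examples
#' pool_spec(c("RM1", "SM1"), c("resistant", "susceptible"), "male", 1)
#' @export
pool_spec <- function(pool_id, phenotype, sex, replicate) {
  df <- data.frame(pool_id = as.character(pool_id),
                   phenotype = match_enum(phenotype, PHENOTYPES, "phenotype"),
                   sex = match_enum(sex, SEXES, "sex"),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$pool_id)) stop_("pool_id values must be unique")
  if (any(df$replicate < 1L)) stop_("replicate must be >= 1")
  class(df) <- c("pool_spec", "data.frame")
  df
}

#' The canonical 8-pool study design
#'
#' Two phenotypes by two sexes by two biological replicates, with the
#' conventional pool codes RM1, RM2, SM1, SM2, RF1, RF2, SF1, SF2
#' (R/S = resistant/susceptible, M/F = male/female).
#'
#' @return A \code{\link{pool_spec}} with 8 rows.
#' @export
canonical_pools <- function() {
  grid <- expand.grid(replicate = 1:2,
                      phenotype = PHENOTYPES,
                      sex = SEXES,
                      stringsAsFactors = FALSE)
  id <- paste0(ifelse(grid$phenotype == "resistant", "R", "S"),
               ifelse(grid$sex == "male", "M", "F"),
               grid$replicate)
  pool_spec(id, grid$phenotype, grid$sex, grid$replicate)
}

# Infer pool metadata from ids like "RM1", "SF2"; returns NULL if any id
# does not follow the convention.
infer_pools_from_ids <- function(ids) {
  ok <- grepl("^[RS][MF][0-9]+$", ids)
  if (!all(ok)) return(NULL)
  pool_spec(ids,
            phenotype = ifelse(substr(ids, 1, 1) == "R",
                               "resistant", "susceptible"),
            sex = ifelse(substr(ids, 2, 2) == "M", "male", "female"),
            replicate = as.integer(substring(ids, 3)))
}

#' Per-pool SNP allele-count table
#'
#' The central pool-seq container: an ordered table of biallelic SNP sites
#' with, for every pool, the number of reads carrying the non-reference
#' (alt) allele and the total read depth.
#'
#' @param sites data frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} (single bases). Rows are sorted by
#'   (chrom, pos) on construction and must be unique.
#' @param pools a \code{\link{pool_spec}} (or data frame coercible to one).
#' @param alt_count,depth integer matrices, sites x pools, with
#'   \code{0 <= alt_count <= depth} elementwise. Column order follows
#'   \code{pools$pool_id}.
#' @return An object of class \code{pooled_snp_table}: a list with elements
#'   \code{sites}, \code{pools}, \code{alt_count}, \code{depth}.
#' @export
pooled_snp_table <- function(sites, pools, alt_count, depth) {
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
    stop_("sites needs columns chrom, pos, ref, alt")
  if (!inherits(pools, "pool_spec"))
    pools <- pool_spec(pools$pool_id, pools$phenotype, pools$sex,
                       pools$replicate)
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos),
                      ref = as.character(sites$ref),
                      alt = as.character(sites$alt),
                      stringsAsFactors = FALSE)
  if (any(sites$pos < 1L)) stop_("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop_("ref and alt alleles must differ")
  alt_count <- as.matrix(alt_count)
  depth <- as.matrix(depth)
  if (!identical(dim(alt_count), dim(depth)) ||
      nrow(alt_count) != nrow(sites) || ncol(alt_count) != nrow(pools))
    stop_("alt_count/depth must be sites x pools matrices")
  if (any(alt_count < 0) || any(depth < 0))
    stop_("counts must be non-negative")
  if (any(alt_count > depth))
    stop_("alt_count exceeds depth at ",
          sum(alt_count > depth), " site/pool cells")
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) stop_("duplicate (chrom, pos) sites")
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  alt_count <- alt_count[o, , drop = FALSE]
  depth <- depth[o, , drop = FALSE]
  dimnames(alt_count) <- dimnames(depth) <- list(NULL, pools$pool_id)
  structure(list(sites = sites, pools = pools,
                 alt_count = alt_count, depth = depth),
            class = "pooled_snp_table")
}

#' @export
print.pooled_snp_table <- function(x, ...) {
  cat(sprintf("pooled_snp_table: %d SNP sites x %d pools (%s)\n",
              nrow(x$sites), nrow(x$pools),
              paste(x$pools$pool_id, collapse = ", ")))
  invisible(x)
}

#' @export
dim.pooled_snp_table <- function(x) c(nrow(x$sites), nrow(x$pools))

#' Composite genotype label codes
#'
#' Two-SNP composite genotype labels used by the qPCR assays for the two
#' validated loci: the label encodes the pair of SNP bases, so heterozygotes
#' get IUPAC-style codes. \code{hom_ref} is the reference homozygote,
#' \code{hom_alt} the non-reference homozygote.
#'
#' @format A named list: for each locus, a character vector mapping states
#'   \code{hom_ref}, \code{het}, \code{hom_alt} to labels.
#' @export
genotype_codes <- list(
  LRRTM4 = c(hom_ref = "GA", het = "RR", hom_alt = "AG"),
  CPQ    = c(hom_ref = "TA", het = "YM", hom_alt = "CC")
)

#' Convert genotype labels to states and back
#'
#' @param label character vector of composite labels (e.g. \code{"RR"}).
#' @param state character vector of states (\code{"hom_ref"}, \code{"het"},
#'   \code{"hom_alt"}).
#' @param locus locus name with an entry in \code{\link{genotype_codes}}, or
#'   a named length-3 character vector giving the mapping directly.
#' @return Character vector of states (or labels).
#' @export
genotype_state <- function(label, locus) {
  map <- locus_code_map(locus)
  st <- names(map)[match(label, map)]
  if (anyNA(st) && !anyNA(label))
    stop_("unknown genotype label(s): ",
          paste(setdiff(label, map), collapse = ", "))
  st
}

#' @rdname genotype_state
#' @export
genotype_label <- function(state, locus) {
  map <- locus_code_map(locus)
  unname(map[match_enum(state, GT_STATES, "genotype state")])
}

locus_code_map <- function(locus) {
  if (is.character(locus) && length(locus) == 1L) {
    if (!locus %in% names(genotype_codes))
      stop_("no genotype code map for locus ", locus)
    genotype_codes[[locus]]
  } else {
    if (!setequal(names(locus), GT_STATES))
      stop_("code map must be named hom_ref, het, hom_alt")
    locus[GT_STATES]
  }
}

#' Individual genotype table
#'
#' Phenotyped individuals with per-locus 3-state genotypes, stored by their
#' composite labels (one column per locus).
#'
#' @param individuals data frame with columns \code{sample_id}, \code{sex}
#'   (\code{male}/\code{female}/\code{unknown}), \code{phenotype}
#'   (\code{resistant}/\code{susceptible}), and one label column per locus.
#' @param loci character vector (length 1 or 2) of locus names; each must be
#'   a column of \code{individuals} and have a code map in
#'   \code{\link{genotype_codes}} (or be supplied via \code{code_maps}).
#' @param code_maps optional named list of label maps for loci not in
#'   \code{\link{genotype_codes}}.
#' @return A data frame of class \code{genotype_table} with attribute
#'   \code{loci}.
#' @export
genotype_table <- function(individuals, loci, code_maps = NULL) {
  if (length(loci) < 1L || length(loci) > 2L)
    stop_("loci must name 1 or 2 loci")
  need <- c("sample_id", "phenotype", loci)
  if (!all(need %in% names(individuals)))
    stop_("individuals needs columns: ", paste(need, collapse = ", "))
  if (is.null(individuals$sex)) individuals$sex <- "unknown"
  df <- data.frame(sample_id = as.character(individuals$sample_id),
                   sex = match_enum(individuals$sex, SEXES_U, "sex"),
                   phenotype = match_enum(individuals$phenotype, PHENOTYPES,
                                          "phenotype"),
                   stringsAsFactors = FALSE)
  maps <- lapply(loci, function(l) {
    if (!is.null(code_maps[[l]])) locus_code_map(code_maps[[l]])
    else locus_code_map(l)
  })
  names(maps) <- loci
  for (l in loci) {
    lab <- as.character(individuals[[l]])
    bad <- !is.na(lab) & !lab %in% maps[[l]]
    if (any(bad))
      stop_("unknown ", l, " genotype label(s): ",
            paste(unique(lab[bad]), collapse = ", "))
    df[[l]] <- lab
  }
  if (anyDuplicated(df$sample_id)) stop_("sample_id values must be unique")
  structure(df, loci = loci, code_maps = maps,
            class = c("genotype_table", "data.frame"))
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, loci: %s\n",
              nrow(x), paste(attr(x, "loci"), collapse = " x ")))
  NextMethod()
}

# Composite class label per individual (concatenated per-locus labels).
composite_label <- function(gt) {
  loci <- attr(gt, "loci")
  lab <- gt[[loci[1L]]]
  if (length(loci) == 2L) lab <- paste0(lab, gt[[loci[2L]]])
  lab[apply(is.na(gt[loci]), 1L, any)] <- NA_character_
  lab
}

#' Chromosome metadata
#'
#' @param name chromosome names.
#' @param length_bp assembly lengths in bp (> 0).
#' @param gc_percent GC content percentage (0-100).
#' @return A data frame of class \code{chromosome_info}.
#' @export
chromosome_info <- function(name, length_bp, gc_percent) {
  df <- data.frame(name = as.character(name),
                   length_bp = as.numeric(length_bp),
                   gc_percent = as.numeric(gc_percent),
                   stringsAsFactors = FALSE)
  if (any(df$length_bp <= 0)) stop_("length_bp must be > 0")
  if (any(df$gc_percent < 0 | df$gc_percent > 100))
    stop_("gc_percent must be in [0, 100]")
  if (anyDuplicated(df$name)) stop_("chromosome names must be unique")
  class(df) <- c("chromosome_info", "data.frame")
  df
}
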