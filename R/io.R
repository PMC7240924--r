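#' Read per-pool SNP allele counts
#'
#' Reads a \code{\link{pooled_snp_table}} from either the package's
#' sync-style TSV dialect or a VCF with per-sample allelic depths (AD).
#'
#' The sync dialect is tab-separated with a header line
#' \code{#chrom pos ref alt <pool_id> <pool_id> ...}; each pool cell is
#' \code{alt:depth}. Pool metadata is taken from \code{pools} if given,
#' otherwise inferred from ids following the RM1/SF2 convention
#' (R/S phenotype, M/F sex, replicate digit).
#'
#' VCF records must be biallelic SNPs; multi-allelic records are dropped
#' with a warning giving their count. A sample with a missing AD field at a
#' site gets depth 0 there (the site is kept, not dropped).
#'
#' @param path input file.
#' @param format \code{"sync"} or \code{"vcf"}.
#' @param pools optional \code{\link{pool_spec}} keyed by the file's pool ids
#'   (sync header / VCF sample names). Required when ids are not inferable.
#' @return A \code{\link{pooled_snp_table}}.
#' @seealso \code{\link{write_pooled_counts}}
#' @export
read_pooled_counts <- function(path, format = c("sync", "vcf"),
                               pools = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("no such file: ", path)
  if (format == "sync") read_sync(path, pools) else read_vcf_counts(path, pools)
}

read_sync <- function(path, pools = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  # provenance stamps: comment lines other than the #chrom header
  lines <- lines[!(startsWith(lines, "#") & !startsWith(lines, "#chrom"))]
  if (!length(lines) || !startsWith(lines[[1L]], "#chrom"))
    stop_("sync file must start with a '#chrom' header line")
  hdr <- strsplit(sub("^#", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 5L || !identical(hdr[1:4], c("chrom", "pos", "ref", "alt")))
    stop_("sync header must be chrom, pos, ref, alt, then pool ids")
  ids <- hdr[-(1:4)]
  pools <- resolve_pools(ids, pools)
  body <- lines[-1L]
  n <- length(body)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(hdr)))
    stop_("malformed sync row at line ", which(nf != length(hdr))[1L] + 1L,
          ": expected ", length(hdr), " fields")
  m <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  sites <- data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
                      ref = m[, 3L], alt = m[, 4L], stringsAsFactors = FALSE)
  if (anyNA(sites$pos))
    stop_("malformed position at line ", which(is.na(sites$pos))[1L] + 1L)
  cells <- m[, -(1:4), drop = FALSE]
  parts <- strsplit(as.vector(cells), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    bad <- (which(lengths(parts) != 2L)[1L] - 1L) %% n + 1L
    stop_("malformed alt:depth cell at line ", bad + 1L)
  }
  num <- suppressWarnings(as.integer(unlist(parts)))
  if (anyNA(num)) {
    bad <- (ceiling(which(is.na(num))[1L] / 2) - 1L) %% n + 1L
    stop_("non-numeric alt:depth cell at line ", bad + 1L)
  }
  alt_count <- matrix(num[c(TRUE, FALSE)], nrow = n)
  depth <- matrix(num[c(FALSE, TRUE)], nrow = n)
  over <- alt_count > depth
  if (any(over))
    stop_("alt_count > depth at line ",
          (which(over)[1L] - 1L) %% n + 2L)
  pooled_snp_table(sites, pools, alt_count, depth)
}

read_vcf_counts <- function(path, pools = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) |
    nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L
  if (any(multi))
    warning(sum(multi), " multi-allelic or non-SNP record(s) dropped",
            call. = FALSE)
  if (all(multi)) stop_("no biallelic SNP records in ", path)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) stop_("VCF has no AD (allelic depth) field")
  keep <- which(!multi)
  ids <- colnames(ad)
  pools <- resolve_pools(ids, pools)
  ad <- ad[keep, , drop = FALSE]
  split2 <- function(x, i) suppressWarnings(
    as.integer(vapply(strsplit(x, ",", fixed = TRUE),
                      function(p) if (length(p) >= i) p[[i]] else NA_character_,
                      character(1L))))
  refd <- apply(ad, 2L, split2, i = 1L)
  altd <- apply(ad, 2L, split2, i = 2L)
  refd <- matrix(refd, nrow = length(keep))
  altd <- matrix(altd, nrow = length(keep))
  # missing AD => depth 0 at that pool, site retained
  refd[is.na(refd)] <- 0L
  altd[is.na(altd)] <- 0L
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                      stringsAsFactors = FALSE)
  pooled_snp_table(sites, pools, altd, refd + altd)
}

resolve_pools <- function(ids, pools) {
  if (is.null(pools)) {
    pools <- infer_pools_from_ids(ids)
    if (is.null(pools))
      stop_("pool metadata not inferable from ids (",
            paste(ids, collapse = ", "),
            "); supply a pool_spec via `pools`")
    return(pools)
  }
  missing <- setdiff(ids, pools$pool_id)
  if (length(missing))
    stop_("unknown pool id(s) in header: ", paste(missing, collapse = ", "))
  pools[match(ids, pools$pool_id), , drop = FALSE]
}

#' Write per-pool SNP allele counts (sync dialect)
#'
#' @param x a \code{\link{pooled_snp_table}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pooled_counts <- function(x, path) {
  stopifnot(inherits(x, "pooled_snp_table"))
  hdr <- paste(c("#chrom", "pos", "ref", "alt", x$pools$pool_id),
               collapse = "\t")
  cells <- matrix(paste(x$alt_count, x$depth, sep = ":"),
                  nrow = nrow(x$sites))
  body <- do.call(paste, c(list(x$sites$chrom, x$sites$pos,
                                x$sites$ref, x$sites$alt),
                           split(cells, col(cells)), sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a frequency-difference track
#'
#' Writes the per-SNP Res-Sus frequency differences of a
#' \code{\link{diff_track}} as an IGV .seg file (1-based inclusive
#' coordinates; the sample column is the sex label) or as bedGraph
#' (0-based half-open, one line per SNP, single sex).
#'
#' @param track a \code{\link{diff_track}}.
#' @param path output file.
#' @param format \code{"seg"} or \code{"bedgraph"}.
#' @param sex which sex's differences to write for bedGraph (required when
#'   the track carries both sexes); ignored for seg, which writes all.
#' @return \code{path}, invisibly.
#' @export
write_diff_track <- function(track, path, format = c("seg", "bedgraph"),
                             sex = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(track, "diff_track"))
  sexes <- track_sexes(track)
  if (nrow(track) == 0L || !length(sexes)) stop_("empty difference track")
  if (format == "seg") {
    rows <- do.call(rbind, lapply(sexes, function(s) {
      d <- track[[paste0("d_", s)]]
      ok <- is.finite(d)
      data.frame(sample = s, chrom = track$chrom[ok], start = track$pos[ok],
                 end = track$pos[ok], value = d[ok],
                 stringsAsFactors = FALSE)
    }))
    if (nrow(rows) == 0L) stop_("no finite values to write")
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    if (is.null(sex)) {
      if (length(sexes) > 1L)
        stop_("track has sexes ", paste(sexes, collapse = ", "),
              "; choose one via `sex` for bedGraph")
      sex <- sexes
    }
    sex <- match_enum(sex, SEXES, "sex")
    d <- track[[paste0("d_", sex)]]
    if (is.null(d)) stop_("track has no ", sex, " differences")
    ok <- is.finite(d)
    if (!any(ok)) stop_("no finite values to write")
    lines <- sprintf("%s\t%d\t%d\t%s", track$chrom[ok],
                     track$pos[ok] - 1L, track$pos[ok],
                     format(d[ok], trim = TRUE, scientific = FALSE))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a written difference track
#'
#' @param path file written by \code{\link{write_diff_track}}.
#' @param format \code{"seg"} or \code{"bedgraph"}.
#' @return A data frame: for seg, columns sample/chrom/start/end/value
#'   (1-based inclusive); for bedGraph, chrom/pos/value with \code{pos}
#'   converted back to 1-based.
#' @export
read_diff_track <- function(path, format = c("seg", "bedgraph")) {
  format <- match.arg(format)
  if (format == "seg") {
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "character", "integer",
                                     "integer", "numeric"))
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "value"),
                            colClasses = c("character", "integer", "integer",
                                           "numeric"))
    data.frame(chrom = df$chrom, pos = df$end, value = df$value,
               stringsAsFactors = FALSE)
  }
}

#' Write candidate regions as BED
#'
#' BED intervals are 0-based half-open; internal coordinates are 1-based
#' inclusive, so start is shifted by one.
#'
#' @param regions a candidate-region data frame with \code{chrom},
#'   \code{start_bp}, \code{stop_bp} columns.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) stop_("no regions to write")
  name <- if (!is.null(regions$direction)) regions$direction
          else sprintf("region%d", seq_len(nrow(regions)))
  lines <- sprintf("%s\t%d\t%d\t%s", regions$chrom,
                   as.integer(regions$start_bp) - 1L,
                   as.integer(regions$stop_bp), name)
  writeLines(lines, path)
  invisible(path)
}

#' Read an individual genotype TSV
#'
#' Expects tab-separated columns \code{sample_id}, \code{sex},
#' \code{phenotype} and one label column per locus.
#'
#' @param path input file.
#' @param loci locus column names (length 1 or 2).
#' @param code_maps optional label maps (see \code{\link{genotype_table}}).
#' @return A \code{\link{genotype_table}}.
#' @export
read_genotype_table <- function(path, loci, code_maps = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  genotype_table(df, loci, code_maps = code_maps)
}

#' @rdname read_genotype_table
#' @param x a \code{\link{genotype_table}} to write.
#' @export
write_genotype_table <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
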