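#' Run the end-to-end synthetic pool-seq scan pipeline
#'
#' Wires the stages together on generated data: simulate a cohort and its
#' pools, sample reads, write the counts (sync dialect), estimate group
#' frequencies, write per-sex difference tracks (.seg and bedGraph), call
#' and classify candidate regions, and write a JSON summary. Every output
#' carries the seed and a configuration hash in its header (or fields), and
#' a rerun with the same configuration is bit-identical.
#'
#' @param config a \code{\link{sim_config}} (its seed drives all
#'   randomness).
#' @param out_dir output directory (created if needed).
#' @param min_depth replicate depth filter for
#'   \code{\link{group_frequencies}}.
#' @param threshold,min_snps,max_gap_bp,merge_bp region-caller settings
#'   (see \code{\link{call_regions}}).
#' @return The summary list, invisibly: counts in/out per stage, region
#'   summary, and file paths.
#' @export
run_pipeline <- function(config, out_dir, min_depth = 10L,
                         threshold = 0.20, min_snps = 10L,
                         max_gap_bp = 20000L, merge_bp = 50000L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_cfg <- list(seed = config$seed, min_depth = min_depth,
                  threshold = threshold, min_snps = min_snps,
                  max_gap_bp = max_gap_bp, merge_bp = merge_bp,
                  n_individuals = config$n_individuals,
                  n_neutral_snps = config$n_neutral_snps,
                  n_qtls = length(config$qtls),
                  mean_depth = config$mean_depth,
                  prevalence_target = config$prevalence_target)
  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(run_cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stamp <- sprintf("# seed=%d config_md5=%s", config$seed, cfg_hash)

  sim <- simulate_poolseq(config)
  sync_path <- file.path(out_dir, "counts.sync.tsv")
  writeLines(stamp, sync_path)
  tmp <- tempfile()
  write_pooled_counts(sim$counts, tmp)
  file.append(sync_path, tmp)
  unlink(tmp)

  freqs <- group_frequencies(sim$counts, min_depth = min_depth)
  track <- diff_track(freqs)
  write_diff_track(track, file.path(out_dir, "diff.seg"), "seg")
  for (s in track_sexes(track))
    write_diff_track(track, file.path(out_dir, paste0("diff_", s, ".bedgraph")),
                     "bedgraph", sex = s)

  regions <- call_regions(track, threshold = threshold, min_snps = min_snps,
                          max_gap_bp = max_gap_bp, merge_bp = merge_bp)
  summary <- list(seed = config$seed, config_md5 = cfg_hash,
                  n_snps = nrow(sim$counts$sites),
                  n_pools = nrow(sim$counts$pools),
                  n_regions = nrow(regions))
  if (nrow(regions) > 0L) {
    regions <- classify_regions(regions)
    rs <- summarize_regions(regions)
    summary$n_chromosomes <- rs$n_chromosomes
    summary$sex_pattern <- as.list(rs$sex_pattern)
    summary$direction <- as.list(rs$direction)
    reg_path <- file.path(out_dir, "regions.tsv")
    writeLines(stamp, reg_path)
    suppressWarnings(utils::write.table(regions, reg_path, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  writeLines(stamp, truth_path)
  if (nrow(sim$truth) > 0L)
    suppressWarnings(utils::write.table(sim$truth, truth_path, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
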