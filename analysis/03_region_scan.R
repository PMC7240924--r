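#!/usr/bin/env Rscript
# Stage 3: deterministic cluster scan over the difference tracks, region
# classification, and comparison of called intervals with the simulation
# truth table.

library(poolqtl)

counts <- read_pooled_counts("results/sim/counts.sync.tsv", "sync")
track <- diff_track(group_frequencies(counts, min_depth = 10L))
regions <- call_regions(track, threshold = 0.20, min_snps = 10L,
                        max_gap_bp = 20000L, merge_bp = 50000L)

out <- "results/regions"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

if (nrow(regions) == 0L) {
  cat("findings: no candidate regions called\n")
} else {
  regions <- classify_regions(regions)
  s <- summarize_regions(regions)
  write.table(regions, file.path(out, "regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_regions_bed(regions, file.path(out, "regions.bed"))
  jsonlite::write_json(
    list(n_regions = s$n_regions, n_chromosomes = s$n_chromosomes,
         sex_pattern = as.list(s$sex_pattern),
         direction = as.list(s$direction)),
    file.path(out, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  print(s)

  truth <- read.table("results/sim/truth.tsv", header = TRUE, sep = "\t",
                      colClasses = c(chrom = "character"))
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(regions$chrom == truth$chrom[i] &
          regions$start_bp <= truth$stop_bp[i] &
          regions$stop_bp >= truth$start_bp[i]), TRUE)
  cat(sprintf("findings: %d/%d implanted blocks overlapped by a called region\n",
              sum(hit), nrow(truth)))
  print(regions[, c("chrom", "start_bp", "stop_bp", "n_snps_male",
                    "n_snps_female", "male_diff_pct", "female_diff_pct",
                    "sex_pattern", "direction")])
}
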