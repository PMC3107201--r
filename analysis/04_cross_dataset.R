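#!/usr/bin/env Rscript
# Stage 4: cross-dataset comparison — Spearman correlation between the two
# replicate arrays' window means (volcano scoring), and co-occupancy of the
# called peaks with the second factor's peak list within 1.5 kb.
suppressPackageStartupMessages(library(chipwin))

data_dir <- "results/data"
out <- "results"
cfg <- read_run_config(file.path(data_dir, "config.yaml"))

## replicate-vs-replicate windowed correlation (a stand-in for comparing
## against an external windowed data set on the same grid)
probes <- read_probe_table(file.path(data_dir, "probes.tsv"))
per_rep <- lapply(1:2, function(j) {
  p <- probes
  p$mean_ratio <- p[[paste0("ratio_", j)]]
  build_windows(p, cfg$window_size, cfg$window_step)
})
cor_res <- correlate_windows(per_rep[[1]], per_rep[[2]], "replicate_2_vs_1")
jsonlite::write_json(unclass(cor_res), file.path(out, "correlation.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("replicate window correlation: rho = %.2f, score = %.1f (n = %d)\n",
            cor_res$rho, cor_res$score, cor_res$n))

## co-occupancy with the second factor over the tiled promoter universe
tss <- read_tss_table(file.path(data_dir, "tss.tsv"))
universe <- data.frame(
  chrom = tss$chrom,
  start = ifelse(tss$strand == "+", tss$tss - cfg$region_upstream,
                 tss$tss - cfg$region_downstream),
  end = ifelse(tss$strand == "+", tss$tss + cfg$region_downstream,
               tss$tss + cfg$region_upstream))
second <- read_bed_intervals(file.path(data_dir, "second_factor.bed"))
peaks_bed <- read_bed_intervals(file.path(out, "peaks.bed"))
if (nrow(peaks_bed) > 0) {
  res <- cooccupancy(second, peaks_bed, universe, cfg$cooccupancy_dist)
  jsonlite::write_json(unclass(res), file.path(out, "cooccupancy.json"),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("co-occupied %d | only test %d | only reference %d\n",
              res$co_occupied, res$only_test, res$only_reference))
  cat(sprintf("%.1f%% of second-factor peaks lie within %d bp of a called peak (fold %.1f, p = %.2g)\n",
              res$pct_of_test, cfg$cooccupancy_dist, res$fold_enrichment,
              res$p_value))
} else {
  cat("no called peaks; skipping co-occupancy\n")
}
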