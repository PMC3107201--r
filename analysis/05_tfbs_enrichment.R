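#!/usr/bin/env Rscript
# Stage 5: motif-site enrichment near called peaks by bp counting.
# Training set: 2 kb TSS flanks of peak-bearing promoters; background: the
# remaining flank DNA of all array genes. Per motif, the bp marked in each
# set enter a one-sided Fisher exact test.
suppressPackageStartupMessages(library(chipwin))

data_dir <- "results/data"
out <- "results"
cfg <- read_run_config(file.path(data_dir, "config.yaml"))

tss <- read_tss_table(file.path(data_dir, "tss.tsv"))
track_bed <- read_bed_intervals(file.path(data_dir, "tfbs.bed"))
track <- data.frame(chrom = track_bed$chrom, start = track_bed$start,
                    end = track_bed$end, motif_id = track_bed$name)
peaks_bed <- read_bed_intervals(file.path(out, "peaks.bed"))
peaks <- data.frame(chrom = peaks_bed$chrom,
                    center = floor((peaks_bed$start + peaks_bed$end) / 2),
                    start = peaks_bed$start, end = peaks_bed$end)

sets <- build_training_background(peaks, tss, cfg$tfbs_flank)
cat(sprintf("training %d bp over %d bound promoters; background %d bp\n",
            sets$training_size, length(sets$bound_genes),
            sets$background_size))

enr <- motif_enrichment(track, sets)
utils::write.table(enr, file.path(out, "tfbs_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("top motifs by Fisher p:\n")
print(utils::head(enr[, c("motif_id", "bp_training", "bp_background",
                          "fold", "p_value", "neg_log10_p")], 5),
      row.names = FALSE)

top <- enr$motif_id[1]
asg <- assign_peaks_to_genes(peaks, tss, cfg$region_upstream,
                             cfg$region_downstream)
hit <- genes_with_motif_near_peak(unique(asg$gene_id), asg, track, top,
                                  adj_flank = cfg$heatmap_window / 2)
cat(sprintf("%d of %d peak-bearing genes (%.2f%%) carry %s adjacent to a peak\n",
            hit$count, length(unique(asg$gene_id)), hit$percentage, top))
jsonlite::write_json(list(motif = top, count = hit$count,
                          percentage = hit$percentage),
                     file.path(out, "motif_near_peak.json"),
                     auto_unbox = TRUE, digits = NA)
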