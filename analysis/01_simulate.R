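#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data set with known ground truth.
#
# Emulates the structure of the original experiment: a two-replicate
# promoter tiling array (promoters tiled -2200..+500 bp around each TSS at
# ~100 bp spacing), a 3-replicate expression table with P/A/M flags coupled
# to binding, a second factor sharing a subset of peaks, and a
# conserved-motif track with one motif planted in bound promoters.
suppressPackageStartupMessages(library(chipwin))

cfg <- run_config(rng_seed = 20260921L)
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n_genes <- 500
sim <- simulate_promoter_array(n_genes, fraction_bound = 0.2,
                               effect_size = 1.5, peak_width = 600,
                               noise_sd = 0.3, n_replicates = 2,
                               seed = cfg$rng_seed)
write_probe_table(sim$probes, file.path(out, "probes.tsv"))
write_tss_table(sim$tss, file.path(out, "tss.tsv"))

expr <- simulate_expression(sim$tss$gene_id, fraction_expressed = 0.55,
                            fraction_ambiguous = 0.1, bound_bias = 4,
                            bound_genes = sim$truth$bound$gene_id,
                            seed = cfg$rng_seed + 1L)
write_expression_table(expr, file.path(out, "expression.tsv"))

second <- simulate_second_factor(sim$truth, sim$tss,
                                 cooccupancy_fraction = 0.5,
                                 jitter_sd = 100, n_extra = 60,
                                 cooccupancy_dist = cfg$cooccupancy_dist,
                                 seed = cfg$rng_seed + 2L)
write_bed_intervals(second$intervals, file.path(out, "second_factor.bed"))
sim$truth$cobound_genes <- second$cobound_genes

track <- simulate_tfbs_track(sim$tss, "V$ELK1_02",
                             enriched_genes = sim$truth$bound$gene_id,
                             background_rate = 0.5, flank = cfg$tfbs_flank,
                             seed = cfg$rng_seed + 3L)
write_bed_intervals(track[, c("chrom", "start", "end", "motif_id")],
                    file.path(out, "tfbs.bed"))

write_truth_json(sim$truth, file.path(out, "truth.json"))
write_run_config(cfg, file.path(out, "config.yaml"))

cat(sprintf("simulated %d promoters (%d probes), %d with planted peaks\n",
            n_genes, nrow(sim$probes), nrow(sim$truth$bound)))
cat(sprintf("second factor: %d co-peaks + %d decoys; motif track: %d sites\n",
            length(second$cobound_genes),
            sum(grepl("^decoy", second$intervals$name)), nrow(track)))
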