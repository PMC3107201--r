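# Synthetic generators: geometry, determinism, truth bookkeeping, and the
# statistical behavior the downstream analyses rely on.

test_that("promoter array has the tiled geometry and is seed-deterministic", {
  sim <- simulate_promoter_array(40, 0.25, seed = 11)
  expect_equal(nrow(sim$tss), 40)
  expect_equal(nrow(sim$truth$bound), 10)
  expect_setequal(unique(sim$tss$strand), c("+", "-"))

  # ~28 probes per promoter spanning -2200..+500 around the TSS
  expect_equal(nrow(sim$probes), 40 * 28)
  g <- sim$tss[1, ]
  mid <- floor((sim$probes$start + sim$probes$end) / 2)
  on_g <- grepl(paste0("^", g$gene_id, "_"), sim$probes$probe_id)
  rel <- ifelse(g$strand == "+", 1, -1) * (mid[on_g] - g$tss)
  expect_true(all(rel >= -2220 & rel <= 520))

  # truth peak centers lie within the tiled region
  expect_true(all(sim$truth$bound$offset >= -2200 &
                    sim$truth$bound$offset <= 500))

  sim2 <- simulate_promoter_array(40, 0.25, seed = 11)
  expect_identical(sim, sim2)
  sim3 <- simulate_promoter_array(40, 0.25, seed = 12)
  expect_false(identical(sim$probes$ratio_1, sim3$probes$ratio_1))

  expect_error(simulate_promoter_array(10, 1.5), "fraction_bound")
})

test_that("unbound arrays are pure noise with empty truth", {
  sim <- simulate_promoter_array(60, 0, noise_sd = 0.3, seed = 2)
  expect_equal(nrow(sim$truth$bound), 0)
  expect_lt(abs(mean(sim$probes$ratio_1)), 0.02)
  expect_lt(abs(sd(sim$probes$ratio_1) - 0.3), 0.02)
})

test_that("expression flags partition genes as requested", {
  genes <- sprintf("G%05d", 1:200)
  ex <- simulate_expression(genes, fraction_expressed = 0.5,
                            fraction_ambiguous = 0, seed = 3)
  cl <- classify_expression(ex)
  expect_setequal(unique(cl$status), c("expressed", "unexpressed"))

  ex_all <- simulate_expression(genes, fraction_expressed = 1,
                                fraction_ambiguous = 0, seed = 3)
  expect_true(all(classify_expression(ex_all)$status == "expressed"))

  ex_amb <- simulate_expression(genes, fraction_expressed = 0.4,
                                fraction_ambiguous = 0.3, seed = 4)
  cl_amb <- classify_expression(ex_amb)
  expect_gt(sum(cl_amb$status == "ambiguous"), 0)

  expect_error(simulate_expression(genes, bound_genes = "nope"), "not in the gene list")
  expect_error(simulate_expression(genes, 0.8, 0.4), "sum")
})

test_that("with no binding bias the bound-gene fold enrichment centers on 1", {
  genes <- sprintf("G%05d", 1:300)
  set.seed(99)
  bound <- sample(genes, 60)
  log_folds <- vapply(1:20, function(s) {
    ex <- simulate_expression(genes, 0.5, 0.1, bound_bias = 1,
                              bound_genes = bound, seed = 100 + s)
    cl <- classify_expression(ex)
    res <- bound_gene_enrichment(cl$gene_id[cl$status == "expressed"],
                                 cl$gene_id[cl$status == "unexpressed"],
                                 bound)
    log(res$fold_enrichment)
  }, 0)
  ci <- mean(log_folds) + c(-2, 2) * sd(log_folds) / sqrt(20)
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("second-factor peaks honor the co-occupancy construction", {
  sim <- simulate_promoter_array(200, 1, seed = 5)  # 200 truth peaks
  universe <- data.frame(chrom = sim$tss$chrom,
                         start = pmin(sim$tss$tss - 2200, sim$tss$tss - 500),
                         end = pmax(sim$tss$tss + 500, sim$tss$tss + 2200))

  # fraction 1, no decoys: every copy within 1.5 kb of its truth peak
  sf1 <- simulate_second_factor(sim$truth, sim$tss, 1, jitter_sd = 100,
                                n_extra = 0, seed = 6)
  ctr <- floor((sf1$intervals$start + sf1$intervals$end) / 2)
  d <- chipwin:::min_dist_to_positions(sf1$intervals$chrom, ctr,
                                       sim$truth$bound$chrom,
                                       sim$truth$bound$center)
  expect_true(all(d < 1500))
  expect_equal(length(sf1$cobound_genes), 200)

  # fraction 0.5: exactly half the truth peaks are copied
  sf_half <- simulate_second_factor(sim$truth, sim$tss, 0.5, jitter_sd = 100,
                                    n_extra = 0, seed = 7)
  expect_equal(nrow(sf_half$intervals), 100)

  # fraction 0 with only decoys: no second-factor peak is co-occupied
  sf0 <- simulate_second_factor(sim$truth, sim$tss, 0, n_extra = 50, seed = 8)
  res <- cooccupancy(sf0$intervals, data.frame(chrom = sim$truth$bound$chrom,
                                               center = sim$truth$bound$center),
                     universe, max_dist = 1500)
  expect_equal(res$co_occupied, 0)
})

test_that("motif track plants one 10-bp site per enriched gene", {
  sim <- simulate_promoter_array(30, 0.3, seed = 9)
  enriched <- sim$truth$bound$gene_id
  track <- simulate_tfbs_track(sim$tss, "V$ELK1_02", enriched,
                               background_rate = 0.5, seed = 10)
  expect_true(all(track$end - track$start == 10))
  expect_equal(sum(track$motif_id == "V$ELK1_02"), length(enriched))

  empty <- simulate_tfbs_track(sim$tss, "V$ELK1_02", character(0),
                               background_rate = 0, seed = 10)
  expect_equal(nrow(empty), 0)
})

test_that("synthetic truth round-trips through JSON", {
  sim <- simulate_promoter_array(25, 0.4, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  back <- read_truth_json(path)
  expect_equal(back$bound$gene_id, sim$truth$bound$gene_id)
  expect_equal(back$bound$center, sim$truth$bound$center)
  expect_equal(back$effect_size, sim$truth$effect_size)
  expect_equal(back$noise_sd, sim$truth$noise_sd)
})

test_that("null arrays keep the per-promoter call rate under the union bound", {
  n_calls <- 0L
  n_promoters <- 0L
  for (s in 1:50) {
    sim <- simulate_promoter_array(20, 0, seed = 2000 + s)
    np <- normalize_probes(sim$probes)
    w <- build_windows(np)
    pk <- call_peaks(w)
    n_calls <- n_calls + nrow(pk)
    n_promoters <- n_promoters + 20L
  }
  # each promoter exposes ~11 candidate window triples; a triple passing
  # needs all three windows below p_threshold, so the union bound
  # p_threshold * n_triples is loose by construction
  expect_lte(n_calls / n_promoters, 0.016 * 11)
})
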