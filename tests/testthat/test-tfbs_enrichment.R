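# TFBS enrichment: interval sets, bp counting, Fisher enrichment.

test_that("training and background partition the all-gene promoter union", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 30
    tss <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      chrom = sample(c("chr1", "chr2"), n, TRUE),
                      strand = "+",
                      tss = sample(seq(3000L, 150000L), n))
    peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 12, TRUE),
                        center = sample.int(150000L, 12))
    sets <- build_training_background(peaks, tss, flank = 2000)
    all_gr <- GenomicRanges::reduce(chipwin:::intervals_to_granges(
      data.frame(chrom = tss$chrom, start = tss$tss - 2000, end = tss$tss + 2000)))
    both <- rbind(sets$training, sets$background)
    union_gr <- GenomicRanges::reduce(chipwin:::intervals_to_granges(both))
    expect_equal(sum(GenomicRanges::width(union_gr)),
                 sum(GenomicRanges::width(all_gr)))
    # disjoint: total bp adds up exactly
    expect_equal(sets$training_size + sets$background_size,
                 sum(GenomicRanges::width(all_gr)))
    if (nrow(sets$training) > 0) {
      ov <- GenomicRanges::intersect(
        chipwin:::intervals_to_granges(sets$training),
        chipwin:::intervals_to_granges(sets$background))
      expect_equal(length(ov), 0)
    }
  }
})

test_that("training set edge cases: no peaks, all genes bound, merged overlaps", {
  tss <- data.frame(gene_id = c("a", "b"), chrom = "chr1", strand = "+",
                    tss = c(10000L, 12000L))  # 2 kb flanks overlap
  none <- build_training_background(data.frame(chrom = character(0),
                                               center = integer(0)), tss)
  expect_equal(nrow(none$training), 0)
  expect_equal(none$background_size, 6000)  # merged [8000,14000)

  both <- build_training_background(
    data.frame(chrom = "chr1", center = c(10000L, 12000L)), tss)
  expect_equal(both$background_size, 0)
  expect_equal(both$training_size, 6000)    # merged union, not 4000 + 4000
  expect_setequal(both$bound_genes, c("a", "b"))
  expect_error(motif_enrichment(data.frame(chrom = "chr1", start = 1L,
                                           end = 11L, motif_id = "m"), both),
               "non-empty")
})

test_that("bp counting clips to regions and merges overlapping sites", {
  regions <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  # fully inside
  expect_equal(count_marked_bp(
    data.frame(chrom = "chr1", start = 150L, end = 160L), regions), 10)
  # straddles the edge: clipped
  expect_equal(count_marked_bp(
    data.frame(chrom = "chr1", start = 195L, end = 210L), regions), 5)
  # two overlapping 10-bp sites offset by 5: union is 15, not 20
  expect_equal(count_marked_bp(
    data.frame(chrom = "chr1", start = c(150L, 155L), end = c(160L, 165L)),
    regions), 15)
})

test_that("bp counts match a per-base bitmap oracle on random inputs", {
  set.seed(72)
  for (rep in 1:10) {
    sites <- data.frame(chrom = "chr1",
                        start = sample.int(9000L, 40))
    sites$end <- sites$start + sample(5:50, 40, TRUE)
    regions <- data.frame(chrom = "chr1", start = c(500L, 4000L, 8000L),
                          end = c(2500L, 6000L, 9500L))
    expect_equal(count_marked_bp(sites, regions),
                 oracle_marked_bp(sites, regions, limit = 10000))
  }
})

test_that("motif enrichment reproduces Fisher oracle values and orderings", {
  sets <- list(training = data.frame(chrom = "chr1", start = 0L, end = 100L),
               background = data.frame(chrom = "chr1", start = 1000L, end = 2000L))
  # equal densities: 10/100 vs 100/1000
  bg_starts <- seq(1000L, 1900L, by = 100L)  # 10 sites x 10 bp = 100 of 1000
  eq_sites <- rbind(
    data.frame(chrom = "chr1", start = 0L, end = 10L, motif_id = "eq"),
    data.frame(chrom = "chr1", start = bg_starts, end = bg_starts + 10L,
               motif_id = "eq"))
  res <- motif_enrichment(eq_sites, sets)
  expect_equal(res$fold[res$motif_id == "eq"], 1)
  expect_gte(res$p_value[res$motif_id == "eq"], 0.5)

  # an explicit table against the oracle: (50, 50; 50, 950)
  sets2 <- list(training = data.frame(chrom = "chr1", start = 0L, end = 100L),
                background = data.frame(chrom = "chr1", start = 1000L, end = 2000L))
  sites2 <- rbind(
    data.frame(chrom = "chr1", start = 0L, end = 50L, motif_id = "m"),
    data.frame(chrom = "chr1", start = 1000L, end = 1050L, motif_id = "m"))
  res2 <- motif_enrichment(sites2, sets2)
  expect_equal(res2$p_value, oracle_fisher_p(50, 50, 50, 950, "greater"),
               tolerance = 1e-10)

  # a motif marking nothing in either set: p = 1
  sites3 <- data.frame(chrom = "chr9", start = 0L, end = 10L, motif_id = "absent")
  res3 <- motif_enrichment(sites3, sets)
  expect_equal(res3$p_value, 1)
  expect_true(is.na(res3$fold))
})

test_that("a planted motif is the most significant in nearly all runs", {
  wins <- 0L
  for (s in 1:20) {
    sim <- simulate_promoter_array(250, 0.25, seed = 700 + s)
    track <- simulate_tfbs_track(sim$tss, "V$ELK1_02",
                                 enriched_genes = sim$truth$bound$gene_id,
                                 background_rate = 0.5, seed = 800 + s)
    peaks <- data.frame(chrom = sim$truth$bound$chrom,
                        center = sim$truth$bound$center)
    sets <- build_training_background(peaks, sim$tss)
    res <- motif_enrichment(track, sets)
    if (res$motif_id[1] == "V$ELK1_02") wins <- wins + 1L
  }
  expect_gte(wins, 18)
})

test_that("motif-near-peak gene counting handles the boundary cases", {
  tss <- data.frame(gene_id = c("a", "b"), chrom = "chr1", strand = "+",
                    tss = c(10000L, 50000L))
  peaks <- data.frame(chrom = "chr1", center = c(10000L, 50000L),
                      start = c(9500L, 49500L), end = c(10500L, 50500L))
  asg <- assign_peaks_to_genes(peaks, tss)

  # site overlapping one peak's adjacency window only
  sites <- data.frame(chrom = "chr1", start = 10250L, end = 10260L,
                      motif_id = "V$ELK1_02")
  res <- genes_with_motif_near_peak(c("a", "b"), asg, sites, "V$ELK1_02")
  expect_equal(res$count, 1)
  expect_equal(res$percentage, 50)
  expect_equal(res$genes, "a")

  # no sites at all
  none <- genes_with_motif_near_peak(c("a", "b"), asg, sites, "V$OTHER_01")
  expect_equal(none$count, 0)
  expect_equal(none$percentage, 0)

  # every bound gene has an overlapping site
  sites2 <- data.frame(chrom = "chr1", start = c(9990L, 49990L),
                       end = c(10010L, 50010L), motif_id = "V$ELK1_02")
  all_hit <- genes_with_motif_near_peak(c("a", "b"), asg, sites2, "V$ELK1_02")
  expect_equal(all_hit$percentage, 100)

  expect_error(genes_with_motif_near_peak(character(0), asg, sites, "x"),
               "non-empty")
})
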