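# TSS-anchored integration and expression classification.

test_that("peak-to-TSS distances are strand-oriented and nearest-by-absolute", {
  tss <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(10000L, 50000L))
  peaks <- data.frame(chrom = "chr1", center = c(10000L, 9500L, 50500L))
  d <- peak_to_tss_distance(peaks, tss)
  expect_equal(d$distance, c(0, -500, -500))  # minus strand flips the sign
  expect_equal(d$gene_id, c("a", "a", "b"))

  # equidistant TSSs break toward the smaller gene_id
  tss2 <- data.frame(gene_id = c("z", "a"), chrom = "chr1",
                     strand = "+", tss = c(1000L, 3000L))
  d2 <- peak_to_tss_distance(data.frame(chrom = "chr1", center = 2000L), tss2)
  expect_equal(d2$gene_id, "a")
})

test_that("nearest-TSS assignment matches the all-pairs oracle", {
  set.seed(51)
  tss <- data.frame(gene_id = sprintf("g%03d", 1:40),
                    chrom = sample(c("chr1", "chr2"), 40, TRUE),
                    strand = sample(c("+", "-"), 40, TRUE),
                    tss = sample.int(1e6, 40))
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                      center = sample.int(1e6, 60))
  d <- peak_to_tss_distance(peaks, tss)
  for (i in seq_len(60)) {
    cand <- tss[tss$chrom == peaks$chrom[i], ]
    d_abs <- abs(peaks$center[i] - cand$tss)
    best <- cand[d_abs == min(d_abs), ]
    best <- best[order(best$gene_id), ][1, ]
    expect_equal(d$gene_id[i], best$gene_id)
    expect_equal(abs(d$distance[i]), min(d_abs))
  }
})

test_that("distance-bin enrichment agrees with the hypergeometric oracle", {
  # peaks exactly proportional to background: nothing enriched
  bg <- rep(seq(-2125, 375, by = 250), times = 10)
  pk <- rep(seq(-2125, 375, by = 250), times = 2)
  res <- tss_distance_enrichment(pk, bg)
  expect_true(all(res$p_value >= 0.5))

  # a concentrated bin reproduces the oracle p for its 2x2 table
  pk2 <- c(rep(-125, 8), rep(-1125, 2))
  bg2 <- c(rep(-125, 10), rep(-1125, 90))
  res2 <- tss_distance_enrichment(pk2, bg2)
  row <- res2[res2$bin_start == -250, ]
  expect_equal(row$n_peaks, 8)
  expect_equal(row$p_value, oracle_fisher_p(8, 2, 10, 90, "greater"),
               tolerance = 1e-10)

  # empty bin on both sides: p = 1
  expect_true(all(res2$p_value[res2$n_peaks == 0 & res2$n_background == 0] == 1))

  expect_error(tss_distance_enrichment(pk2, numeric(0)), "non-empty")
})

test_that("the TSS-anchored matrix has 19 columns and respects strand", {
  sim <- simulate_promoter_array(20, 0, seed = 52)
  probes <- sim$probes
  probes$mean_ratio <- 1
  mat <- tss_anchored_matrix(probes, sim$tss)
  expect_equal(ncol(mat), 19)
  expect_equal(colnames(mat)[1], "-2200")
  expect_equal(colnames(mat)[19], "500")

  # constant probe values give a constant row
  expect_true(all(abs(mat[1, !is.na(mat[1, ])] - 1) < 1e-12))

  # a minus-strand gene with the mirrored layout gives the same row
  tss2 <- data.frame(gene_id = c("fwd", "rev"), chrom = "chrM",
                     strand = c("+", "-"), tss = c(10000L, 50000L))
  off <- seq(-2200, 500, by = 100)
  probes2 <- rbind(
    make_probes_at(10000L + off, off / 1000, chrom = "chrM"),
    make_probes_at(50000L - off, off / 1000, chrom = "chrM"))
  mat2 <- tss_anchored_matrix(probes2, tss2)
  expect_equal(mat2["fwd", ], mat2["rev", ], tolerance = 1e-12)
})

test_that("expression classification follows unanimity of flags", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     signal_1 = c(5, 6, 7), signal_2 = c(5, 6, 7),
                     signal_3 = c(5, 6, 7),
                     flag_1 = c("P", "P", "A"), flag_2 = c("P", "A", "A"),
                     flag_3 = c("P", "P", "A"), stringsAsFactors = FALSE)
  cl <- classify_expression(expr)
  expect_equal(cl$status, c("expressed", "ambiguous", "unexpressed"))
  expect_equal(cl$mean_signal, c(5, 6, 7))

  expr$flag_2[1] <- "Q"
  expect_error(classify_expression(expr), "\\{P,A,M\\}")
})

test_that("deciles partition genes with sizes differing by at most one", {
  genes <- sprintf("g%03d", 1:23)
  expr <- data.frame(gene_id = genes, signal_1 = seq_len(23),
                     flag_1 = "P", stringsAsFactors = FALSE)
  cl <- classify_expression(expr)
  sizes <- table(cl$decile)
  expect_equal(sum(sizes), 23)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(cl$decile[which.min(cl$mean_signal)], 1L)
  expect_equal(cl$decile[which.max(cl$mean_signal)], 10L)

  # 20 genes: exactly 2 per decile; identical rows give identical profiles
  mat <- matrix(0.5, nrow = 20, ncol = 19,
                dimnames = list(sprintf("g%03d", 1:20), NULL))
  prof <- decile_profile(mat, cl)
  expect_equal(nrow(prof), 10)
  expect_true(all(abs(prof - 0.5) < 1e-12))

  expect_error(decile_profile(mat[1:5, ], cl), "at least 10")
})

test_that("decile profile maxima rise with expression when binding is biased", {
  # a moderate odds bias mixes bound genes across the expression range,
  # giving the graded decile profile the analysis is meant to expose
  rhos <- vapply(1:10, function(s) {
    sim <- simulate_promoter_array(300, 0.4, seed = 300 + s)
    np <- normalize_probes(sim$probes)
    mat <- tss_anchored_matrix(np, sim$tss)
    ex <- simulate_expression(sim$tss$gene_id, 0.5, 0.1, bound_bias = 4,
                              bound_genes = sim$truth$bound$gene_id,
                              seed = 400 + s)
    cl <- classify_expression(ex)
    prof <- decile_profile(mat, cl)
    peak_height <- apply(prof, 1, max, na.rm = TRUE)
    cor(1:10, peak_height, method = "spearman")
  }, 0)
  expect_gt(mean(rhos), 0.8)
})

test_that("bound-gene enrichment reproduces known contingency results", {
  # printed-count scenario: 516 of 5696 expressed vs 77 of 4333 unexpressed
  expressed <- sprintf("e%04d", 1:5696)
  unexpressed <- sprintf("u%04d", 1:4333)
  bound <- c(expressed[1:516], unexpressed[1:77])
  res <- bound_gene_enrichment(expressed, unexpressed, bound)
  expect_equal(round(res$fold_enrichment, 1), 5.1)
  expect_equal(round(res$pct_expressed_bound, 1), 9.1)
  expect_equal(round(res$pct_unexpressed_bound, 1), 1.8)
  expect_lt(res$p_value, 1e-50)

  # equal rates: fold 1, two-sided p = 1
  eq <- bound_gene_enrichment(sprintf("e%d", 1:100), sprintf("u%d", 1:100),
                              c(sprintf("e%d", 1:50), sprintf("u%d", 1:50)))
  expect_equal(eq$fold_enrichment, 1)
  expect_gte(eq$p_value, 0.999)

  # perfectly separated 10/10: p = 2 / C(20, 10)
  sep <- bound_gene_enrichment(sprintf("e%d", 1:10), sprintf("u%d", 1:10),
                               sprintf("e%d", 1:10))
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-10)

  expect_error(bound_gene_enrichment(character(0), "u1", "x"), "non-empty")
  expect_error(bound_gene_enrichment(c("a", "b"), c("b", "c"), "x"), "disjoint")
})

test_that("peaks are assigned to every containing promoter", {
  tss <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                    strand = "+", tss = c(10000L, 10400L))  # overlapping promoters
  peaks <- data.frame(chrom = "chr1", center = c(9500L, 30000L))
  asg <- assign_peaks_to_genes(peaks, tss)
  expect_setequal(asg$gene_id, c("a", "b"))   # peak 9500 in both promoters
  expect_true(all(asg$center == 9500))
})
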