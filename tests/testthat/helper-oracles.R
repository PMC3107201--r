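# Independent brute-force oracles used to check the package's statistics,
# plus small fixture builders. Oracles deliberately use the most direct
# possible computation, not the package's code paths.

# One-sided signed-rank p by direct enumeration of all 2^n sign
# assignments: for each assignment, the positive-rank sum is recomputed and
# compared with the observed one.
oracle_signrank_p <- function(values, direction = "greater") {
  v <- values[values != 0]
  n <- length(v)
  if (n == 0) return(1)
  r <- rank(abs(v))
  w_obs <- sum(r[v > 0])
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    w <- sum(r[signs])
    ok <- if (direction == "greater") w >= w_obs - 1e-9 else w <= w_obs + 1e-9
    if (ok) hits <- hits + 1L
  }
  hits / 2^n
}

# Fisher exact p for table (a, b; c, d) by direct hypergeometric summation.
oracle_fisher_p <- function(a, b, c, d, sided = "two.sided") {
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  n <- row1 + row2
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- dhyper(support, row1, row2, col1)
  p_obs <- dhyper(a, row1, row2, col1)
  if (sided == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

# Two-sided Spearman permutation p by exhaustive enumeration of all n!
# orderings, recomputing rho from scratch each time.
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  rho_obs <- cor(x, y, method = "spearman")
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  hits <- 0L
  total <- 0L
  for (p in perm_rec(seq_len(n))) {
    rho <- cor(x, y[p], method = "spearman")
    total <- total + 1L
    if (abs(rho) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# Union length of intervals intersected with a region set, by marking
# individual bases in a logical vector.
oracle_marked_bp <- function(sites, regions, limit = 2e5) {
  stopifnot(max(c(sites$end, regions$end)) <= limit)
  site_mask <- logical(limit)
  for (i in seq_len(nrow(sites))) {
    site_mask[(sites$start[i] + 1):sites$end[i]] <- TRUE
  }
  region_mask <- logical(limit)
  for (i in seq_len(nrow(regions))) {
    region_mask[(regions$start[i] + 1):regions$end[i]] <- TRUE
  }
  sum(site_mask & region_mask)
}

# Probe table from explicit midpoints and per-probe mean ratios (one
# replicate, 20 bp probes) for window/caller tests.
make_probes_at <- function(midpoints, values, chrom = "chr1") {
  df <- data.frame(chrom = chrom, start = midpoints - 10L,
                   end = midpoints + 10L,
                   probe_id = sprintf("p%03d", seq_along(midpoints)),
                   ratio_1 = values, stringsAsFactors = FALSE)
  df$mean_ratio <- values
  df
}

# Window table with a given sequence of means on a regular grid, all
# windows passing the probe-count and p criteria (for caller logic tests).
make_windows_from_means <- function(means, step = 250L, window_size = 1000L,
                                    chrom = "chr1", n_probes = 10L,
                                    p_value = 0.001) {
  centers <- step * seq_along(means)
  data.frame(chrom = chrom, center = centers,
             start = as.integer(centers - window_size / 2),
             end = as.integer(centers + window_size / 2),
             n_probes = n_probes, mean = means, p_value = p_value,
             stringsAsFactors = FALSE)
}
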