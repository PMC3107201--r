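# Cross-dataset comparison: windowed Spearman correlation with volcano
# scoring, and peak co-occupancy within a distance threshold.

#' Spearman correlation between two window tables
#'
#' Windows are matched on identical (chrom, center); pairs missing a mean
#' in either set are dropped. Rho uses midranks. The p-value is two-sided:
#' exact by enumeration of all n! rank permutations for n <= 9, otherwise
#' the t-approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of
#' freedom. The volcano score is -log10(p), capped at 320.
#'
#' @param a,b window data.frames (chrom, center, mean) on the same grid.
#' @param dataset_id label for the comparison.
#' @return list of class `correlation_result`: dataset_id, rho, p_value,
#'   score (capped -log10 p), signed_score (score carrying rho's sign), n.
#' @export
correlate_windows <- function(a, b, dataset_id = "dataset") {
  m <- merge(a[, c("chrom", "center", "mean")],
             b[, c("chrom", "center", "mean")],
             by = c("chrom", "center"), suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m$mean_a, m$mean_b), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) stop("correlation undefined: fewer than 3 shared windows")
  rho <- stats::cor(m$mean_a, m$mean_b, method = "spearman")
  p <- spearman_p(m$mean_a, m$mean_b, rho)
  score <- min(-log10(max(p, 1e-320)), 320)
  structure(list(dataset_id = dataset_id, rho = rho, p_value = p,
                 score = score, signed_score = sign(rho) * score, n = n),
            class = "correlation_result")
}

# Two-sided p for a Spearman rho: exact permutation for n <= 9, else
# t-approximation.
spearman_p <- function(x, y, rho = stats::cor(x, y, method = "spearman")) {
  n <- length(x)
  if (n <= 9) {
    rx <- rank(x); ry <- rank(y)
    u <- rx - mean(rx); v <- ry - mean(ry)
    denom <- sqrt(sum(u^2) * sum(v^2))
    if (denom == 0) return(1)
    perms <- all_permutations(n)
    stat <- as.vector(matrix(v[perms], nrow(perms), n) %*% u) / denom
    mean(abs(stat) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) return(2 * stats::pt(-Inf, n - 2) + 1e-320)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
}

#' Peak co-occupancy within a distance threshold
#'
#' Both peak sets are first reduced to centers and filtered to the tiled
#' universe. A test peak is co-occupied iff a reference peak center on the
#' same chromosome lies within `max_dist` bp. The null for fold enrichment
#' and the Fisher test discretizes the universe into `max_dist`-bp bins: a
#' bin is reference-adjacent iff its midpoint is within `max_dist` of a
#' reference center, and uniform placement of test peaks over bins gives
#' the expected co-occupancy rate. Fisher table: (co-occupied, only test;
#' adjacent bins, non-adjacent bins), two-sided.
#'
#' @param test_peaks,reference_peaks data.frames with chrom, start, end (or
#'   chrom, center).
#' @param universe data.frame of tiled intervals (chrom, start, end).
#' @param max_dist co-occupancy radius, bp.
#' @return list of class `cooccupancy_result`: co_occupied, only_test,
#'   only_reference, pct_of_test, pct_of_reference, fold_enrichment,
#'   p_value, expected_rate, n_bins.
#' @export
cooccupancy <- function(test_peaks, reference_peaks, universe,
                        max_dist = 1500L) {
  if (nrow(universe) == 0) stop("universe must be non-empty")
  tc <- peak_centers(test_peaks)
  rc <- peak_centers(reference_peaks)
  tc <- filter_to_universe(tc, universe)
  rc <- filter_to_universe(rc, universe)

  d_test <- min_dist_to_positions(tc$chrom, tc$center, rc$chrom, rc$center)
  co <- sum(d_test <= max_dist)
  only_test <- nrow(tc) - co
  d_ref <- min_dist_to_positions(rc$chrom, rc$center, tc$chrom, tc$center)
  co_ref <- sum(d_ref <= max_dist)
  only_reference <- nrow(rc) - co_ref

  bins <- universe_bins(universe, max_dist)
  adj <- min_dist_to_positions(bins$chrom, bins$mid, rc$chrom, rc$center) <= max_dist
  n_adj <- sum(adj)
  expected_rate <- n_adj / nrow(bins)
  fold <- if (expected_rate > 0 && nrow(tc) > 0) {
    (co / nrow(tc)) / expected_rate
  } else NA_real_
  p <- contingency_result(co, only_test, n_adj, nrow(bins) - n_adj,
                          sided = "two.sided")$p_value

  structure(list(co_occupied = co, only_test = only_test,
                 only_reference = only_reference,
                 pct_of_test = 100 * co / max(co + only_test, 1),
                 pct_of_reference = 100 * co / max(co + only_reference, 1),
                 fold_enrichment = fold, p_value = p,
                 expected_rate = expected_rate, n_bins = nrow(bins)),
            class = "cooccupancy_result")
}

#' Co-occupancy percentages from bare counts
#'
#' Rebuilds the percentage columns of a co-occupancy table from its counts:
#' `pct_of_test = 100 co / (co + only_test)` and `pct_of_reference =
#' 100 co / (co + only_reference)` (the count of reference peaks near a
#' test peak equals co when test and reference pair one-to-one).
#'
#' @param co_occupied,only_test,only_reference non-negative counts.
#' @return list: counts plus pct_of_test and pct_of_reference.
#' @export
cooccupancy_from_counts <- function(co_occupied, only_test, only_reference) {
  if (any(c(co_occupied, only_test, only_reference) < 0)) {
    stop("counts must be non-negative")
  }
  list(co_occupied = co_occupied, only_test = only_test,
       only_reference = only_reference,
       pct_of_test = 100 * co_occupied / (co_occupied + only_test),
       pct_of_reference = 100 * co_occupied / (co_occupied + only_reference))
}

peak_centers <- function(peaks) {
  ctr <- if ("center" %in% names(peaks)) peaks$center else
    probe_midpoint(peaks$start, peaks$end)
  data.frame(chrom = peaks$chrom, center = ctr, stringsAsFactors = FALSE)
}

filter_to_universe <- function(centers, universe) {
  keep <- logical(nrow(centers))
  for (ch in unique(centers$chrom)) {
    ci <- which(centers$chrom == ch)
    ui <- which(universe$chrom == ch)
    if (length(ui) == 0) next
    for (i in ci) {
      keep[i] <- any(centers$center[i] >= universe$start[ui] &
                     centers$center[i] < universe$end[ui])
    }
  }
  centers[keep, , drop = FALSE]
}

universe_bins <- function(universe, bin_size) {
  chroms <- character(0); mids <- numeric(0)
  for (i in seq_len(nrow(universe))) {
    len <- universe$end[i] - universe$start[i]
    n <- ceiling(len / bin_size)
    s <- universe$start[i] + (seq_len(n) - 1) * bin_size
    e <- pmin(s + bin_size, universe$end[i])
    chroms <- c(chroms, rep(universe$chrom[i], n))
    mids <- c(mids, (s + e) / 2)
  }
  data.frame(chrom = chroms, mid = mids, stringsAsFactors = FALSE)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: rho = %.3f, p = %s, score = %.2f (n = %d windows)\n",
              x$dataset_id, x$rho, format(x$p_value, digits = 3),
              x$score, x$n))
  invisible(x)
}

#' @export
print.cooccupancy_result <- function(x, ...) {
  cat(sprintf("co-occupied %d | only test %d | only reference %d\n",
              x$co_occupied, x$only_test, x$only_reference))
  cat(sprintf("%% of test %.1f | %% of reference %.1f | fold %s | p = %s\n",
              x$pct_of_test, x$pct_of_reference,
              if (is.na(x$fold_enrichment)) "NA" else
                format(x$fold_enrichment, digits = 3),
              format(x$p_value, digits = 3)))
  invisible(x)
}
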